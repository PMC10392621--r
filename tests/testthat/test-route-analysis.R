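# route_analysis: folding heatmaps, backtracking detection, region
# selection and contact maps, route assignment, commitment, fraying

test_that("foldingHeatmap bins frames and averages per-residue local Q_o", {
  nat <- toyNative()
  ens <- routeEnsemble(nat, routeSpec(1:3), 24, seed = 40L,
                       stages = 0:3)
  hm <- foldingHeatmap(ens, nat, nBins = 10L)
  expect_s4_class(hm, "FoldingHeatmap")
  expect_equal(dim(heatmapMatrix(hm)), c(45L, 10L))
  expect_equal(sum(binCounts(hm)), 24L)
  expect_equal(hm@binEdges, seq(0, 1, length.out = 11L))
  # independent recomputation for one occupied bin
  cp <- contactPairs(nat@contacts)
  perFrame <- lapply(frames(ens), function(f) {
    X <- coords(f)
    term <- vapply(seq_len(nrow(cp)), function(k) {
      r <- sqrt(sum((X[cp$i[k], ] - X[cp$j[k], ])^2))
      1 / (1 + exp(5 * (r - 1.2 * cp$nativeDist[k])))
    }, numeric(1))
    res <- vapply(1:45, function(res) {
      rows <- cp$i == res | cp$j == res
      if (!any(rows)) NA_real_ else mean(term[rows])
    }, numeric(1))
    list(global = mean(term), local = res)
  })
  g <- vapply(perFrame, `[[`, numeric(1), "global")
  b <- which.max(binCounts(hm))
  inBin <- g > hm@binEdges[b] & g <= hm@binEdges[b + 1] |
           (b == 1 & g >= 0 & g <= hm@binEdges[2])
  ref <- rowMeans(vapply(perFrame[inBin], `[[`, numeric(45), "local"))
  expect_equal(heatmapMatrix(hm)[, b], ref, tolerance = 1e-9)
  expect_error(foldingHeatmap(ens, nat, nBins = 1L), "at least 2 bins")
})

test_that("detectBacktracking flags exactly the planted drop", {
  mkHeat <- function(M, counts) {
    new("FoldingHeatmap", binEdges = seq(0, 1, length.out = ncol(M) + 1L),
        matrix = M, counts = as.integer(counts))
  }
  # residue 1 monotone, residue 2 drops 0.35 from bin 2 to bin 5
  M <- rbind(seq(0.1, 0.9, length.out = 6),
             c(0.10, 0.60, 0.45, 0.35, 0.25, 0.90))
  hm <- mkHeat(M, rep(20L, 6))
  out <- detectBacktracking(hm, minDrop = 0.2, minSpan = 2L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$residue, 2L)
  expect_equal(out$binStart, 2L)
  expect_equal(out$binEnd, 5L)
  expect_equal(out$drop, 0.35, tolerance = 1e-12)
  # monotone rows are never flagged
  expect_equal(nrow(detectBacktracking(mkHeat(M[1, , drop = FALSE],
                                              rep(20L, 6)))), 0L)
  # an under-populated bin is excluded before comparison
  out2 <- detectBacktracking(mkHeat(M, c(20L, 3L, 20L, 20L, 20L, 20L)),
                             minDrop = 0.2, minCount = 10L)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$binStart, 3L)   # bin 2 no longer eligible
  expect_equal(out2$drop, 0.45 - 0.25, tolerance = 1e-12)
  # minSpan excludes adjacent-bin noise
  M3 <- rbind(c(0.1, 0.6, 0.3, 0.65, 0.7, 0.9))
  expect_equal(nrow(detectBacktracking(mkHeat(M3, rep(20L, 6)),
                                       minDrop = 0.2, minSpan = 3L)), 0L)
  expect_error(detectBacktracking(mkHeat(M, c(20L, rep(2L, 5)))),
               "occupied columns")
})

test_that("selectRegion applies the even-odd rule with boundary inclusion", {
  pts <- rbind(c(0.5, 0.5),   # inside
               c(2.0, 2.0),   # outside
               c(1.0, 0.5),   # on the right edge
               c(0.0, 0.0),   # vertex
               c(0.25, 0.75)) # inside
  proj <- new("Projection", coords = pts, repOf = c(1L, 2L, 3L, 4L, 5L, 1L),
              representatives = 1:5, stress = 0.01, stressAbs = 0.01,
              stressTrace = 0.01, seed = 0L, iterationsRun = 1L)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sel <- selectRegion(proj, sq)
  expect_equal(sel@representatives, c(1L, 3L, 4L, 5L))
  # frame 6 maps to representative 1, so it is a member too
  expect_equal(memberFrames(sel), c(1L, 3L, 4L, 5L, 6L))
  far <- rbind(c(10, 10), c(11, 10), c(10.5, 11))
  expect_error(selectRegion(proj, far), "no representatives")
  expect_error(selectRegion(proj, sq[1:2, ]), ">= 3")
})

test_that("regionContactMap equals contactMap on the member frames", {
  set.seed(801)
  nat <- toyNative()
  fr <- lapply(1:8, function(k)
    conformation(coords(nat) + matrix(rnorm(135, sd = k / 3), ncol = 3)))
  ens <- ensemble(fr)
  proj <- elvim(ens, seed = 1L)
  box <- rbind(apply(coords(proj), 2, min) - 1,
               c(apply(coords(proj), 2, max) + 1),
               c(apply(coords(proj)[, 1, drop = FALSE], 2, max) + 1,
                 apply(coords(proj)[, 2, drop = FALSE], 2, min) - 1))
  sel <- selectRegion(proj, rbind(box[1, ], c(box[2, 1], box[1, 2]),
                                  box[2, ], c(box[1, 1], box[2, 2])))
  expect_equal(memberFrames(sel), 1:8)   # bounding box catches everything
  cm <- regionContactMap(sel, ens)
  expect_equal(cm, contactMap(ens))
  sel2 <- new("RegionSelection", polygon = box, representatives = 1:3,
              frames = c(2L, 5L))
  expect_equal(regionContactMap(sel2, ens),
               contactMap(ensemble(fr[c(2, 5)])))
})

test_that("assignRoutes separates N-terminal from C-terminal routes", {
  nat <- toyNative()
  eN <- routeEnsemble(nat, routeSpec(1:3), 15, seed = 50L, stages = 2L)
  eC <- routeEnsemble(nat, routeSpec(3:1), 15, seed = 51L, stages = 2L)
  band <- c(0.25, 0.8)
  aN <- assignRoutes(eN, nat, stageBand = band)
  aC <- assignRoutes(eC, nat, stageBand = band)
  expect_gt(nrow(aN), 10L)
  expect_gt(nrow(aC), 10L)
  expect_gt(mean(aN$label == "N"), 0.9)
  expect_gt(mean(aC$label == "C"), 0.9)
  expect_error(assignRoutes(eN, nat, stageBand = c(0.5, 0.2)), "interval")
  expect_error(assignRoutes(eN, nat, stageBand = c(0.98, 1)),
               "no frames inside")
})

test_that("commitment from native seeds is certain with an exact CP interval", {
  nat <- toyNative()
  p <- goModelParams()
  res <- commitment(nat@native, nat, p, threshold = 0.5, budget = 1000L,
                    nReplicas = 6L, seed = 2L, stride = 100L)
  expect_s4_class(res, "CommitmentResult")
  expect_equal(commitmentFraction(res), 1)
  expect_equal(res@nFolded, 6L)
  expect_equal(res@nAborted, 0L)
  # Clopper-Pearson closed form at k = n
  expect_equal(commitmentCI(res), c(qbeta(0.025, 6, 1), 1),
               tolerance = 1e-12)
  # named groups return a named list and are seeded independently
  both <- commitment(list(a = list(nat@native), b = list(nat@native)),
                     nat, p, threshold = 0.5, budget = 600L,
                     nReplicas = 3L, seed = 2L, stride = 100L)
  expect_named(both, c("a", "b"))
  expect_equal(commitmentFraction(both$a), 1)
  expect_error(commitment(nat@native, nat, p, threshold = 1.2), "threshold")
  expect_error(commitment(nat@native, nat, p, budget = 0L), "budget")
})

test_that("frayingProfile recovers the planted fraying rate exactly", {
  nat <- toyNative()
  ens <- frayedEnsemble(nat, 200L, frayRate = 0.3, seed = 7L)
  fp <- frayingProfile(ens, nat)
  expect_named(fp, c("R1", "R2", "R3"))
  # frozen: the planted 60/200 fraction is recovered without error
  expect_equal(unname(fp), c(0, 0, 0.3), tolerance = 1e-12)
  # fraying another repeat moves the stripe, not the rate
  ens2 <- frayedEnsemble(nat, 60L, frayRepeat = 1L, frayRate = 0.25,
                         seed = 8L)
  fp2 <- frayingProfile(ens2, nat)
  expect_equal(unname(fp2[1]), 0.25, tolerance = 1e-12)
  expect_equal(unname(fp2[2:3]), c(0, 0))
  expect_error(frayingProfile(ens, nat, globalQMin = 0), "in \\(0, 1\\)")
  expect_error(frayingProfile(ens, nat, globalQMin = 0.999),
               "no frames with global")
})
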