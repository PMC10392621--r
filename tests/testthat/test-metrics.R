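# metrics: internal-distance similarity q / Q_w, local q, dissimilarity
# matrices, smoothed fraction of native contacts Q_o, contact maps, Rg

test_that("pairSimilarity matches the brute-force double loop", {
  for (s in c(1, 2, 3)) {
    set.seed(400 + s)
    n <- 5 + 7 * s
    A <- randomChain(n); B <- randomChain(n)
    expect_equal(pairSimilarity(conformation(A), conformation(B)),
                 oracleQ(A, B), tolerance = 1e-12)
    # non-default parameters change sigma_ij and the pair set consistently
    p <- metricParams(sigma0 = 1.7, epsilon = 0.3, minSepQ = 5L)
    expect_equal(pairSimilarity(conformation(A), conformation(B), p),
                 oracleQ(A, B, sigma0 = 1.7, epsilon = 0.3, minSep = 5),
                 tolerance = 1e-12)
  }
})

test_that("similarity is 1 at identity and equals its frozen value on the canonical pair", {
  set.seed(404)
  A <- randomChain(20)
  expect_identical(pairSimilarity(conformation(A), conformation(A)), 1)
  # canonical 5-residue pair: straight chain vs terminal residue displaced
  # 2 A off-axis; value frozen from the independent oracle
  A <- cbind(3.8 * (0:4), 0, 0)
  B <- A; B[5, ] <- B[5, ] + c(0, 2, 0)
  expect_equal(pairSimilarity(conformation(A), conformation(B)),
               0.9945038995, tolerance = 1e-9)
})

test_that("q and Q_o are invariant under rigid motion", {
  set.seed(405)
  nat <- toyNative()
  X <- coords(nat) + matrix(rnorm(3 * nResidues(nat)), ncol = 3)
  Xr <- randomRigid(X)
  a <- conformation(X); b <- conformation(Xr)
  expect_equal(qw(a, nat), qw(b, nat), tolerance = 1e-9)
  expect_equal(fractionNativeContacts(a, nat),
               fractionNativeContacts(b, nat), tolerance = 1e-9)
  expect_equal(localQ(a, nat, focus = 1:15), localQ(b, nat, focus = 1:15),
               tolerance = 1e-9)
  expect_equal(radiusOfGyration(a), radiusOfGyration(b), tolerance = 1e-9)
})

test_that("localQ matches its oracle and is NA when no pair qualifies", {
  set.seed(406)
  nat <- toyNative()
  X <- coords(nat) + matrix(rnorm(3 * nResidues(nat), sd = 2), ncol = 3)
  a <- conformation(X)
  for (focus in list(3L, 1:15, 31:45))
    expect_equal(localQ(a, nat, focus = focus),
                 oracleLocalQ(X, coords(nat), focus), tolerance = 1e-12)
  # 5-residue bent chain: qualifying pairs are (1,4), (1,5), (2,5);
  # residue 3 touches none of them -> NA, never 0
  X5 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
              c(0, 7.6, 0))
  tinyRef <- nativeReference(conformation(X5), cbind(1L, 5L))
  expect_true(is.na(localQ(conformation(X5), tinyRef, focus = 3L)))
  expect_error(localQ(conformation(X5), tinyRef, focus = 9L),
               "out of range")
})

test_that("dissimilarityMatrix agrees entrywise with 1 - pairwise oracle q", {
  set.seed(407)
  frames <- lapply(1:6, function(k) randomChain(12))
  ens <- ensemble(lapply(frames, conformation))
  delta <- dissimilarityValues(dissimilarityMatrix(ens))
  expect_equal(dim(delta), c(6L, 6L))
  expect_identical(diag(delta), rep(0, 6))
  expect_equal(delta, t(delta), tolerance = 1e-15)
  for (k in 1:5) for (l in (k + 1):6)
    expect_equal(delta[k, l], 1 - oracleQ(frames[[k]], frames[[l]]),
                 tolerance = 1e-12)
})

test_that("fractionNativeContacts matches the oracle and closed forms", {
  set.seed(408)
  nat <- toyNative()
  X <- coords(nat) + matrix(rnorm(3 * nResidues(nat)), ncol = 3)
  cp <- contactPairs(nat@contacts)
  expect_equal(fractionNativeContacts(conformation(X), nat),
               oracleQo(X, cbind(cp$i, cp$j), cp$nativeDist),
               tolerance = 1e-12)
  # single contact at exactly lambda * r0 gives 1/2; at lambda*r0 - 6/beta
  # it gives 1/(1 + e^-6). Use a 10-residue chain with one contact (1, 10).
  r0 <- 7.5
  cs <- new("ContactSet", pairs = cbind(1L, 10L), nativeDist = r0)
  place <- function(r) {
    X <- cbind(seq(0, r, length.out = 10), 0, 0)
    conformation(X)
  }
  p <- metricParams()
  expect_equal(fractionNativeContacts(place(1.2 * r0), cs, p), 0.5,
               tolerance = 1e-12)
  expect_equal(fractionNativeContacts(place(1.2 * r0 - 6 / 5), cs, p),
               1 / (1 + exp(-6)), tolerance = 1e-12)
  # frozen native value of the 3 x 15 toy array
  expect_equal(fractionNativeContacts(nat@native, nat), 0.9989942720,
               tolerance = 1e-9)
})

test_that("Q_o decreases strictly under uniform expansion", {
  nat <- toyNative()
  vals <- vapply(c(1, 1.05, 1.15, 1.3), function(s)
    fractionNativeContacts(conformation(coords(nat) * s), nat), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("localFractionNativeContacts averages each residue's own contacts", {
  set.seed(409)
  nat <- toyNative()
  X <- coords(nat) + matrix(rnorm(3 * nResidues(nat)), ncol = 3)
  prof <- profileValues(localFractionNativeContacts(conformation(X), nat))
  cp <- contactPairs(nat@contacts)
  for (res in c(1L, 8L, 23L, 45L)) {
    rows <- which(cp$i == res | cp$j == res)
    if (length(rows) == 0L) { expect_true(is.na(prof[res])); next }
    terms <- vapply(rows, function(k) {
      r <- sqrt(sum((X[cp$i[k], ] - X[cp$j[k], ])^2))
      1 / (1 + exp(5 * (r - 1.2 * cp$nativeDist[k])))
    }, numeric(1))
    expect_equal(prof[res], mean(terms), tolerance = 1e-12)
  }
  # a residue in no native contact is NA, not 0
  cs <- new("ContactSet", pairs = cbind(1L, 10L), nativeDist = 7.5)
  p2 <- profileValues(localFractionNativeContacts(
    conformation(cbind(seq(0, 9, 1), 0, 0)), cs))
  expect_true(all(is.na(p2[2:9])))
  expect_false(anyNA(p2[c(1, 10)]))
})

test_that("contactMap reproduces the hard-cutoff occupancy oracle", {
  set.seed(410)
  frames <- lapply(1:4, function(k) randomChain(9, scale = 5))
  cm <- contactMap(ensemble(lapply(frames, conformation)))
  ora <- oracleContactMap(frames)
  expect_equal(nrow(cm), nrow(ora))
  expect_equal(cm$i, ora[, 1])
  expect_equal(cm$j, ora[, 2])
  expect_equal(cm$prob, ora[, 3], tolerance = 1e-12)
  expect_true(all(cm$j - cm$i > 3))
})

test_that("radiusOfGyration has its closed-form value on simple bodies", {
  # two points 2 A apart: each is 1 A from the centroid
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  set.seed(411)
  X <- randomChain(17)
  expect_equal(radiusOfGyration(conformation(X)), oracleRg(X),
               tolerance = 1e-12)
})

test_that("ensembleMetrics columns agree with the per-frame functions", {
  set.seed(412)
  nat <- toyNative()
  fr <- lapply(1:5, function(k)
    conformation(coords(nat) + matrix(rnorm(3 * 45, sd = k / 2), ncol = 3)))
  ens <- ensemble(fr)
  em <- ensembleMetrics(ens, nat)
  expect_equal(names(em)[1:4], c("frame", "Qw", "Qo", "Rg"))
  for (k in 1:5) {
    expect_equal(em$Qw[k], qw(fr[[k]], nat), tolerance = 1e-12)
    expect_equal(em$Qo[k], fractionNativeContacts(fr[[k]], nat),
                 tolerance = 1e-12)
    expect_equal(em$Rg[k], radiusOfGyration(fr[[k]]), tolerance = 1e-12)
    for (r in 1:3)
      expect_equal(em[[paste0("q_R", r)]][k],
                   localQ(fr[[k]], nat, focus = (15 * (r - 1) + 1):(15 * r)),
                   tolerance = 1e-12)
  }
})

test_that("size and pair-subset contracts are enforced", {
  a <- conformation(randomChain(8)); b <- conformation(randomChain(9))
  expect_error(pairSimilarity(a, b), "differ in residue count")
  expect_error(pairSimilarity(a, a, pairSubset = cbind(1L, 3L)),
               "minimum separation")
  expect_error(pairSimilarity(a, a,
                              pairSubset = matrix(integer(0), 0, 2)),
               "empty")
  expect_error(dissimilarityMatrix(ensemble(list(a))), "at least 2 frames")
})
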