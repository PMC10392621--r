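# synthetic_data: toy natives, route/mixture/frayed ensembles, Go model,
# Langevin dynamics, 1D Brownian sampler

test_that("the toy native is deterministic with audited contact topology", {
  a <- buildToyNative(3L, 15L)
  b <- buildToyNative(3L, 15L)
  expect_identical(coords(a), coords(b))
  expect_equal(nResidues(a), 45L)
  expect_equal(nRepeats(a), 3L)
  expect_equal(repeatRanges(a)[, "start"], c(1L, 16L, 31L),
               ignore_attr = TRUE)
  # frozen size of the native contact set
  expect_equal(nContacts(a), 223L)
  # contacts are intra-repeat or between chain-adjacent repeats only
  cp <- contactPairs(a@contacts)
  repOf <- rep(1:3, each = 15)
  expect_true(all(abs(repOf[cp$j] - repOf[cp$i]) <= 1))
  for (r in 1:2)
    expect_true(any(repOf[cp$i] == r & repOf[cp$j] == r + 1))
  # the split taper gives a per-repeat intra-contact gradient R1 < R2 < R3
  intra <- vapply(1:3, function(r)
    sum(repOf[cp$i] == r & repOf[cp$j] == r), integer(1))
  expect_true(all(diff(intra) > 0))
  expect_equal(intra, c(16L, 21L, 25L))
})

test_that("the toy native scores as fully folded and its strands are bonded", {
  nat <- toyNative()
  expect_identical(qw(nat@native, nat), 1)
  expect_equal(fractionNativeContacts(nat@native, nat), 0.9989942720,
               tolerance = 1e-9)
  # consecutive C-alpha spacing stays within physical virtual-bond range
  d <- sqrt(rowSums((coords(nat)[-1, ] - coords(nat)[-45, ])^2))
  expect_true(all(d >= 3.8 - 1e-9))
  expect_lt(max(d), 10)
  # parameter audit errors fire for broken geometries
  expect_error(buildToyNative(3L, 15L, repeatSep = 3),
               "non-adjacent repeats")
  expect_error(buildToyNative(3L, 15L, repeatSep = 13),
               "no interface contacts")
  expect_error(buildToyNative(1L, 15L), "at least 2 repeats")
  expect_error(buildToyNative(3L, 5L), "at least 8 residues")
})

test_that("routeEnsemble is seeded-reproducible and labelled", {
  nat <- toyNative()
  spec <- routeSpec(1:3)
  e1 <- routeEnsemble(nat, spec, 12, seed = 5L)
  e2 <- routeEnsemble(nat, spec, 12, seed = 5L)
  expect_identical(coords(getFrame(e1, 7)), coords(getFrame(e2, 7)))
  e3 <- routeEnsemble(nat, spec, 12, seed = 6L)
  expect_false(identical(coords(getFrame(e1, 7)), coords(getFrame(e3, 7))))
  sc <- scalars(e1)
  expect_named(sc, c("frame", "route", "stage", "progress", "qw", "qo"))
  expect_true(all(sc$route == "R1>R2>R3"))
  expect_true(all(sc$stage == floor(sc$progress)))
  expect_true(all(sc$progress >= 0 & sc$progress <= 3))
  expect_error(routeEnsemble(nat, routeSpec(1:2), 5), "permutation")
})

test_that("folded repeats track the native and coil repeats do not", {
  nat <- toyNative()
  # stage 1 of the N-route: repeat 1 folded, repeats 2-3 coil
  ens <- routeEnsemble(nat, routeSpec(1:3), 10, seed = 9L, stages = 1L)
  em <- ensembleMetrics(ens, nat)
  # the per-repeat local q includes interface pairs with coil partners, so
  # even a perfectly folded repeat is diluted; the folded repeat must still
  # clearly dominate the coil repeat in every frame
  expect_true(all(em$q_R1 > em$q_R3))
  expect_true(all(em$q_R3 < 0.4))
  # restricted to intra-repeat pairs, the folded repeat is near-native
  p <- metricParams()
  qp <- foldscape:::.qualifyingPairs(45L, p@minSepQ)
  intraR1 <- qp[qp[, 2L] <= 15L, , drop = FALSE]
  qIntra <- vapply(frames(ens), function(f)
    pairSimilarity(f, nat@native, p, pairSubset = intraR1), numeric(1))
  expect_true(all(qIntra > 0.8))
  # the global coordinate grows with the folding stage
  means <- vapply(0:3, function(s)
    mean(scalars(routeEnsemble(nat, routeSpec(1:3), 6, seed = 30L + s,
                               stages = s))$qo), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 0.15)   # coil leaves few native contacts formed
  expect_gt(means[4], 0.85)
})

test_that("coil stretches keep bond lengths and avoid hard clashes", {
  nat <- toyNative()
  ens <- routeEnsemble(nat, routeSpec(1:3), 5, seed = 13L, stages = 0L)
  for (f in frames(ens)) {
    X <- coords(f)
    d <- sqrt(rowSums((X[-1, ] - X[-45, ])^2))
    expect_equal(d, rep(3.8, 44), tolerance = 1e-9)
    # restricted turn angle: successive bond directions within 60 degrees
    u <- (X[-1, ] - X[-45, ]) / 3.8
    expect_true(all(rowSums(u[-1, ] * u[-44, ]) >= 0.5 - 1e-9))
  }
})

test_that("mixtureEnsemble mixes seeded route draws in stated proportions", {
  nat <- toyNative()
  specs <- list(routeSpec(1:3, weight = 0.5), routeSpec(3:1, weight = 0.5))
  m1 <- mixtureEnsemble(specs, nat, 40, seed = 3L)
  m2 <- mixtureEnsemble(specs, nat, 40, seed = 3L)
  expect_identical(scalars(m1)$route, scalars(m2)$route)
  expect_identical(coords(getFrame(m1, 11)), coords(getFrame(m2, 11)))
  tab <- table(scalars(m1)$route)
  expect_equal(sort(names(tab)), c("R1>R2>R3", "R3>R2>R1"))
  expect_true(all(tab >= 10))          # both routes materially present
  expect_identical(scalars(m1)$frame, 1:40)
  bad <- list(routeSpec(1:3, weight = 0.7), routeSpec(3:1, weight = 0.5))
  expect_error(mixtureEnsemble(bad, nat, 10), "sum to 1")
  expect_error(mixtureEnsemble(specs[1], nat, 10), "at least 2")
})

test_that("frayedEnsemble plants an exact fray count that is measurable", {
  nat <- toyNative()
  ens <- frayedEnsemble(nat, 50, frayRate = 0.26, seed = 4L)
  sc <- scalars(ens)
  expect_equal(sum(sc$frayed), round(0.26 * 50))
  em <- ensembleMetrics(ens, nat)
  # frayed frames lose repeat-3 structure but keep repeats 1-2
  expect_true(all(em$q_R3[sc$frayed] < 0.5))
  expect_true(all(em$q_R3[!sc$frayed] > 0.5))
  expect_true(all(em$q_R1 > 0.5))
})

test_that("the Go energy has its closed-form native value and exact gradient", {
  nat <- toyNative()
  p <- goModelParams()
  atNative <- goEnergy(nat@native, nat, p)
  # bonds at native lengths, contacts at well bottoms, excluded volume
  # inactive: E = -depth * N_contacts exactly
  expect_equal(atNative$energy, -p@contactDepth * nContacts(nat),
               tolerance = 1e-12)
  expect_lt(max(abs(atNative$gradient)), 1e-10)
  # finite-difference gradient check off the minimum
  set.seed(700)
  X <- coords(nat) + matrix(rnorm(135, sd = 0.4), ncol = 3)
  g <- goEnergy(conformation(X), nat, p)$gradient
  h <- 1e-6
  for (pick in list(c(3L, 1L), c(20L, 2L), c(45L, 3L))) {
    Xp <- X; Xp[pick[1], pick[2]] <- Xp[pick[1], pick[2]] + h
    Xm <- X; Xm[pick[1], pick[2]] <- Xm[pick[1], pick[2]] - h
    num <- (goEnergy(conformation(Xp), nat, p)$energy -
            goEnergy(conformation(Xm), nat, p)$energy) / (2 * h)
    expect_equal(g[pick[1], pick[2]], num, tolerance = 1e-4)
  }
  expect_error(goEnergy(conformation(randomChain(10)), nat),
               "differ in residue count")
})

test_that("langevinRun is seeded-deterministic and records coordinates", {
  nat <- toyNative()
  p <- goModelParams()
  r1 <- langevinRun(nat@native, nat, p, nsteps = 500L, stride = 100L,
                    seed = 2L)
  r2 <- langevinRun(nat@native, nat, p, nsteps = 500L, stride = 100L,
                    seed = 2L)
  expect_identical(coords(getFrame(runEnsemble(r1), 5)),
                   coords(getFrame(runEnsemble(r2), 5)))
  sc <- scalars(runEnsemble(r1))
  expect_named(sc, c("frame", "energy", "qw", "qo"))
  expect_equal(nrow(sc), 5L)
  # the recorded q_w matches the metrics module on the recorded frames
  for (k in c(1L, 5L))
    expect_equal(sc$qw[k], qw(getFrame(runEnsemble(r1), k), nat),
                 tolerance = 1e-9)
  # near-native start at moderate temperature stays near-native
  expect_true(all(sc$qw > 0.8))
  r3 <- langevinRun(nat@native, nat, p, nsteps = 500L, stride = 100L,
                    seed = 3L)
  expect_false(identical(scalars(runEnsemble(r3))$qw, sc$qw))
})

test_that("a biased run is pulled toward the umbrella center", {
  nat <- toyNative()
  p <- goModelParams()
  low <- langevinRun(nat@native, nat, p, nsteps = 6000L, stride = 50L,
                     seed = 8L, bias = c(0.55, 1000))
  qwS <- scalars(runEnsemble(low))$qw
  # an unbiased run from the native stays near q_w ~ 1; the bias drags the
  # chain most of the way to its center
  expect_lt(mean(tail(qwS, 40)), 0.8)
  expect_gt(mean(tail(qwS, 40)), 0.4)
})

test_that("the simulator approximately respects equipartition on bonds", {
  # overdamped harmonic mode: Var(r - r0) -> kT / k_eff. Use a stiff-bond
  # chain with no contacts driving compaction, small dt for low Euler bias.
  nat <- toyNative()
  p <- goModelParams(contactDepth = 0, dt = 2e-4)
  run <- langevinRun(nat@native, nat, p, nsteps = 150000L, stride = 50L,
                     seed = 12L, temperature = 300)
  devs <- unlist(lapply(frames(runEnsemble(run))[-(1:500)], function(f) {
    X <- coords(f)
    sqrt(rowSums((X[-1, ] - X[-45, ])^2)) -
      sqrt(rowSums((coords(nat)[-1, ] - coords(nat)[-45, ])^2))
  }))
  # k_bond = 100 kT/A^2 at kT = 1: sd = 0.1 A; excluded volume stiffens
  # some bonds slightly, so allow 15%
  expect_equal(sd(devs), 0.1, tolerance = 0.15)
})

test_that("umbrellaScan chains windows and discards equilibration", {
  nat <- toyNative()
  p <- goModelParams()
  ws <- umbrellaScan(nat, p, centers = c(0.9, 0.7), kSpring = 1000,
                     nsteps = 2000L, stride = 50L, seed = 3L)
  expect_length(ws, 2L)
  expect_equal(vapply(ws, function(w) w@center, numeric(1)), c(0.9, 0.7))
  # discard = 0.1 of 40 recorded samples leaves 36
  expect_equal(lengths(lapply(ws, function(w) w@samples)), c(36L, 36L))
  expect_true(all(unlist(lapply(ws, function(w) w@samples)) > 0))
})

test_that("meltScan returns an ascending-temperature melting table", {
  nat <- toyNative()
  p <- goModelParams()
  # 30k steps: the 700 K leg needs time to melt from its chained start
  # (second-half mean qw ~0.3 there, vs ~0.45-0.52 at 10k steps)
  df <- meltScan(nat, p, temperatures = c(200, 700), nsteps = 30000L,
                 stride = 50L, seed = 1L, nReplicas = 1L)
  expect_named(df, c("temperature", "meanQw"))
  expect_equal(df$temperature, c(200, 700))
  # cold run stays folded; hot run melts
  expect_gt(df$meanQw[1], 0.7)
  expect_lt(df$meanQw[2], 0.5)
})

test_that("analytic 1D potentials have their closed-form values", {
  dw <- doubleWellPotential(height = 4)
  expect_equal(dw$f(0), 0)
  expect_equal(dw$f(1), 0)
  expect_equal(dw$f(0.5), 4)
  expect_equal(dw$grad(0.5), 0)
  expect_equal(dw$grad(0), 0)
  hp <- harmonicPotential(kappa = 3, x0 = 0.2)
  expect_equal(hp$f(1.2), 1.5)
  expect_equal(hp$grad(1.2), 3)
  # numeric derivative agreement off the stationary points
  h <- 1e-6
  expect_equal(dw$grad(0.3), (dw$f(0.3 + h) - dw$f(0.3 - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("brownian1d equilibrates to the biased Boltzmann variance", {
  pot <- harmonicPotential(kappa = 4, x0 = 0)
  ws <- brownian1d(pot, data.frame(center = 0, kSpring = 6),
                   nsteps = 200000L, seed = 21L, dt = 0.002, burnin = 0.1)
  # total stiffness 10: Var = kT / 10
  expect_equal(var(ws[[1]]@samples), 1 / 10, tolerance = 0.05)
  expect_equal(mean(ws[[1]]@samples), 0, tolerance = 0.02)
  ws2 <- brownian1d(pot, data.frame(center = 0, kSpring = 6),
                    nsteps = 1000L, seed = 21L)
  expect_s4_class(ws2[[1]], "UmbrellaWindow")
})
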