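# ---------------------------------------------------------------------------
# toy native geometry
# ---------------------------------------------------------------------------

#' Build a toy repeat-protein native structure
#'
#' Deterministic hairpin-solenoid C-alpha geometry: each repeat is a
#' two-strand hairpin (strands `strandSep` apart), and successive repeats
#' stack side by side `repeatSep` apart with alternating orientation, so
#' each repeat forms intra-repeat (cross-strand) contacts and interface
#' contacts only with its chain neighbours. Because contacts bridge
#' strands, they span large sequence separations, which a random coil
#' rarely closes — giving the unfolded state a low fraction of native
#' contacts, as in real repeat arrays.
#'
#' The hairpin strand split is tapered linearly from `splitHigh` (first
#' repeat, lopsided hairpin, fewer contacts) to `splitLow` (last repeat,
#' balanced hairpin, more contacts). Real repeat arrays are quasi- but not
#' exactly symmetric, and this mild stability gradient is what lets
#' mirror-image folding routes reach the same global coordinate with
#' different structures.
#'
#' @param nRepeats number of repeats (>= 2).
#' @param residuesPerRepeat residues per repeat (>= 8).
#' @param strandSep cross-strand spacing within a hairpin, Angstrom
#'   (default 4.8).
#' @param repeatSep lateral spacing between adjacent repeats, Angstrom
#'   (default 6.2; non-adjacent repeats sit at >= 2 x `repeatSep`, beyond
#'   the contact cutoff).
#' @param splitHigh,splitLow fraction of each repeat's residues on the
#'   first hairpin strand, tapered across repeats (defaults 0.68 and 0.52;
#'   equal values give an exactly symmetric array).
#' @param bondLength consecutive C-alpha spacing within a strand, Angstrom
#'   (default 3.8; turn and junction bonds are longer and taken from the
#'   built geometry).
#' @param params [MetricParams-class]; sets the contact cutoff.
#' @return A [NativeReference-class] with repeat boundaries recorded.
#' @export
buildToyNative <- function(nRepeats, residuesPerRepeat, strandSep = 4.8,
                           repeatSep = 6.2, splitHigh = 0.68,
                           splitLow = 0.52, bondLength = 3.8,
                           params = metricParams()) {
  if (nRepeats < 2L) stop("need at least 2 repeats")
  if (residuesPerRepeat < 8L) stop("need at least 8 residues per repeat")
  splits <- seq(splitHigh, splitLow, length.out = nRepeats)
  m <- residuesPerRepeat
  n <- nRepeats * m
  xyz <- matrix(0, n, 3L)
  zStart <- 0
  idx <- 1L
  for (r in seq_len(nRepeats)) {
    h1 <- round(m * splits[r])
    h1 <- min(max(h1, 2L), m - 2L)
    h2 <- m - h1
    if (h1 < h2) stop("split fraction must keep the first strand longest")
    p <- (r - 1L) %% 2L
    x <- (r - 1L) * repeatSep
    yA <- p * strandSep
    yB <- (1L - p) * strandSep
    for (k in seq_len(h1)) {          # first strand, ascending z
      xyz[idx, ] <- c(x, yA, zStart + (k - 1L) * bondLength)
      idx <- idx + 1L
    }
    for (k in seq_len(h2)) {          # return strand, descending z
      xyz[idx, ] <- c(x, yB, zStart + (h1 - k) * bondLength)
      idx <- idx + 1L
    }
    zStart <- zStart + (h1 - h2) * bondLength  # next repeat continues here
  }
  repeats <- cbind(start = seq(1L, n, by = residuesPerRepeat),
                   end = seq(residuesPerRepeat, n, by = residuesPerRepeat))
  native <- nativeReference(conformation(xyz), repeats, params)
  # repeat-of-residue lookup and adjacency audit of the contact set
  repOf <- rep(seq_len(nRepeats), each = residuesPerRepeat)
  ri <- repOf[native@contacts@pairs[, 1L]]
  rj <- repOf[native@contacts@pairs[, 2L]]
  if (any(abs(ri - rj) > 1L))
    stop("geometry produces contacts between non-adjacent repeats; ",
         "increase repeatSep or shorten the cutoff")
  for (r in seq_len(nRepeats - 1L))
    if (!any(ri == r & rj == r + 1L))
      stop("geometry produces no interface contacts between repeats ",
           r, " and ", r + 1L, "; decrease repeatSep")
  native
}

# ---------------------------------------------------------------------------
# coil generation and route-structured ensembles
# ---------------------------------------------------------------------------

# fixed-bond-length random walk with soft excluded volume and capped turn
# angle (successive step directions deviate by at most maxTurn, mimicking
# the restricted virtual bond angles of a C-alpha chain): draws directions
# until the new position clears `exclRadius` of every placed atom except the
# attachment atom; after maxReject rejections the step is accepted anyway.
.walkStep <- function(from, placed, bondLength, exclRadius,
                      prevDir = NULL, cosMin = 0.5, maxReject = 100L) {
  cand <- from
  for (t in seq_len(maxReject + 1L)) {
    repeat {
      v <- rnorm(3L)
      v <- v / sqrt(sum(v * v))
      if (is.null(prevDir) || sum(v * prevDir) >= cosMin) break
    }
    cand <- from + bondLength * v
    if (nrow(placed) == 0L) return(cand)
    d2 <- rowSums(sweep(placed, 2L, cand)^2)
    if (all(d2 >= exclRadius^2) || t > maxReject) return(cand)
  }
  cand
}

# build one frame: folded residues at native + jitter, each unfolded stretch
# replaced by a random walk grafted at the chain junction
.routeFrame <- function(native, foldedResidues, noise, bondLength = 3.8,
                        exclRadius = 4.0) {
  n <- nResidues(native)
  xyz <- matrix(NA_real_, n, 3L)
  folded <- logical(n)
  folded[foldedResidues] <- TRUE
  if (any(folded))
    xyz[folded, ] <- native@native@coords[folded, , drop = FALSE] +
      matrix(rnorm(3L * sum(folded), sd = noise), ncol = 3L)
  runs <- rle(folded)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    a <- starts[k]; b <- ends[k]
    if (a > 1L) {                       # graft forward from the left
      seqIdx <- a:b; fromIdx <- a - 1L
    } else if (b < n) {                 # graft backward from the right
      seqIdx <- b:a; fromIdx <- b + 1L
    } else {                            # fully unfolded chain
      seqIdx <- a:b; fromIdx <- NA_integer_
    }
    prev <- if (is.na(fromIdx)) c(0, 0, 0) else xyz[fromIdx, ]
    if (is.na(fromIdx)) {
      xyz[seqIdx[1L], ] <- prev
      seqIdx <- seqIdx[-1L]
    }
    prevDir <- NULL
    for (i in seqIdx) {
      placed <- xyz[!is.na(xyz[, 1L]) & seq_len(n) != i, , drop = FALSE]
      # drop the attachment atom from the clash check (it is bonded)
      keep <- rowSums(sweep(placed, 2L, prev)^2) > 1e-12
      xyz[i, ] <- .walkStep(prev, placed[keep, , drop = FALSE], bondLength,
                            exclRadius, prevDir)
      prevDir <- (xyz[i, ] - prev) / bondLength
      prev <- xyz[i, ]
    }
  }
  conformation(xyz)
}

#' Generate a route-structured synthetic ensemble
#'
#' Frames are drawn across folding stages of one repeat-by-repeat route: at
#' stage s the first s repeats in the route order sit at their native
#' coordinates plus Gaussian jitter, while the remaining repeats are replaced
#' by a fixed-bond-length random coil with soft excluded volume, grafted at
#' the chain junction. Route and stage labels are stored in frame metadata
#' and in the scalar table together with per-frame Q_w and Q_o.
#'
#' @param native a [NativeReference-class].
#' @param spec a [RouteSpec-class]; its order must be a permutation of the
#'   native's repeats.
#' @param nFrames total frames.
#' @param seed integer seed.
#' @param stages folding stages to sample (stage s = s repeats folded).
#'   A single value gives discrete frames exactly at that stage; a range
#'   samples a continuous folding progress uniformly between its extremes,
#'   with the next repeat in the route order partially grown from its
#'   junction with the folded block — so the global coordinate advances by
#'   genuine folding progress, as along a real trajectory, rather than by
#'   coil fluctuations alone. Default 0..nRepeats (the full route).
#' @param params [MetricParams-class] for the recorded coordinates.
#' @return A labelled [Ensemble-class]; the scalar table carries `route`,
#'   integer `stage`, continuous `progress`, `qw` and `qo` per frame.
#' @export
routeEnsemble <- function(native, spec, nFrames, seed = 1L,
                          stages = 0:nRepeats(native),
                          params = metricParams()) {
  R <- nRepeats(native)
  if (length(spec@order) != R)
    stop("route order must be a permutation of the native's ", R, " repeats")
  reps <- .repeatMembers(native)
  frames <- vector("list", nFrames)
  progress <- numeric(nFrames)
  .seedGuard(seed, {
    progress[] <- if (length(stages) == 1L) rep(stages, nFrames)
                  else sort(runif(nFrames, min(stages), max(stages)))
    for (f in seq_len(nFrames)) {
      s <- floor(progress[f])
      frac <- progress[f] - s
      foldedReps <- spec@order[seq_len(s)]
      foldedResidues <- unlist(reps[foldedReps])
      if (frac > 0 && s < R) {
        nxt <- spec@order[s + 1L]
        rng <- reps[[nxt]]
        k <- round(frac * length(rng))
        if (k > 0L) {
          # grow the partial repeat from its junction with the folded block
          fromStart <- (nxt - 1L) %in% foldedReps ||
                       !((nxt + 1L) %in% foldedReps)
          part <- if (fromStart) rng[seq_len(k)]
                  else rng[seq.int(length(rng) - k + 1L, length(rng))]
          foldedResidues <- c(foldedResidues, part)
        }
      }
      frames[[f]] <- .routeFrame(native, foldedResidues, spec@noiseFolded)
      frames[[f]]@meta <- list(route = spec@label, stage = s,
                               progress = progress[f])
    }
  })
  ens <- ensemble(frames)
  em <- ensembleMetrics(ens, native, params)
  ens@scalars <- data.frame(frame = seq_len(nFrames), route = spec@label,
                            stage = floor(progress), progress = progress,
                            qw = em$Qw, qo = em$Qo)
  ens
}

#' Mix route-structured ensembles in stated proportions
#'
#' Draws each frame's route from the specs' mixture weights (seeded, so the
#' composition is deterministic), generates each route with the same stage
#' allocation so the global-coordinate marginals overlap, and retains route
#' labels per frame.
#'
#' @param specs list of >= 2 [RouteSpec-class] whose weights sum to 1.
#' @param native a [NativeReference-class].
#' @param nFrames total frames.
#' @param seed integer seed.
#' @param stages stages to sample (default 0..nRepeats).
#' @param params [MetricParams-class].
#' @return A labelled [Ensemble-class].
#' @export
mixtureEnsemble <- function(specs, native, nFrames, seed = 1L,
                            stages = 0:nRepeats(native),
                            params = metricParams()) {
  if (length(specs) < 2L) stop("need at least 2 route specs")
  w <- vapply(specs, function(s) s@weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    stop("mixture weights must sum to 1 (got ", sum(w), ")")
  routeOf <- .seedGuard(seed,
    sample.int(length(specs), nFrames, replace = TRUE, prob = w))
  parts <- lapply(seq_along(specs), function(r) {
    nr <- sum(routeOf == r)
    if (nr == 0L) return(NULL)
    routeEnsemble(native, specs[[r]], nr, seed = seed + 1000L * r,
                  stages = stages, params = params)
  })
  frames <- vector("list", nFrames)
  scal <- vector("list", nFrames)
  taken <- integer(length(specs))
  for (f in seq_len(nFrames)) {
    r <- routeOf[f]
    taken[r] <- taken[r] + 1L
    frames[[f]] <- parts[[r]]@frames[[taken[r]]]
    scal[[f]] <- parts[[r]]@scalars[taken[r], ]
  }
  ens <- ensemble(frames)
  sc <- do.call(rbind, scal)
  sc$frame <- seq_len(nFrames)
  rownames(sc) <- NULL
  ens@scalars <- sc
  ens
}

#' Near-native ensemble with planted terminal fraying
#'
#' All frames carry the full array at native coordinates plus jitter; in a
#' planted fraction of frames one repeat is replaced by random coil
#' ("frayed"). The planted per-frame fray labels are stored in the scalar
#' table.
#'
#' @param native a [NativeReference-class].
#' @param nFrames total frames.
#' @param frayRepeat repeat index to fray (default the last repeat).
#' @param frayRate fraction of frames frayed (planted exactly, rounded).
#' @param noise Angstrom jitter on folded repeats (default 0.5).
#' @param seed integer seed.
#' @param params [MetricParams-class].
#' @return An [Ensemble-class] with `frayed` in its scalar table.
#' @export
frayedEnsemble <- function(native, nFrames, frayRepeat = nRepeats(native),
                           frayRate = 0.3, noise = 0.5, seed = 1L,
                           params = metricParams()) {
  reps <- .repeatMembers(native)
  nFray <- round(frayRate * nFrames)
  frames <- vector("list", nFrames)
  frayed <- logical(nFrames)
  .seedGuard(seed, {
    frayed[sample.int(nFrames, nFray)] <- TRUE
    for (f in seq_len(nFrames)) {
      foldedReps <- if (frayed[f]) setdiff(seq_along(reps), frayRepeat)
                    else seq_along(reps)
      frames[[f]] <- .routeFrame(native, unlist(reps[foldedReps]), noise)
    }
  })
  ens <- ensemble(frames)
  em <- ensembleMetrics(ens, native, params)
  ens@scalars <- data.frame(frame = seq_len(nFrames), frayed = frayed,
                            qw = em$Qw, qo = em$Qo)
  ens
}

# ---------------------------------------------------------------------------
# Go model and Langevin dynamics
# ---------------------------------------------------------------------------

# 0-based topology arrays for the C++ kernel
.goTopology <- function(native, p, params = metricParams()) {
  n <- nResidues(native)
  xyz <- native@native@coords
  bi <- seq_len(n - 1L); bj <- bi + 1L
  br0 <- .pairDistances(xyz, bi, bj)   # structure-based bond lengths
  cp <- native@contacts@pairs
  allPairs <- .qualifyingPairs(n, 2L)
  key <- function(m) m[, 1L] * (n + 1L) + m[, 2L]
  excl <- allPairs[!(key(allPairs) %in% key(cp)), , drop = FALSE]
  qp <- .qualifyingPairs(n, params@minSepQ)
  list(bi = bi - 1L, bj = bj - 1L, br0 = br0,
       ci = cp[, 1L] - 1L, cj = cp[, 2L] - 1L,
       cr0 = native@contacts@nativeDist,
       ei = excl[, 1L] - 1L, ej = excl[, 2L] - 1L,
       qi = qp[, 1L] - 1L, qj = qp[, 2L] - 1L,
       qr0 = .pairDistances(xyz, qp[, 1L], qp[, 2L]),
       q2s2 = 2 * .sigma2(qp, params))
}

#' Energy and gradient of the additive C-alpha Go potential
#'
#' E = sum_bonds k/2 (r - r0)^2
#'   + sum_contacts -depth exp(-(r - r0)^2 / (2 width^2))
#'   + sum_non-native, r < excludedRadius, k_ex/2 (excludedRadius - r)^2,
#' with bond and contact reference distances taken from the native structure,
#' in kT at the reference temperature. The native structure is a stationary
#' point (the excluded-volume term is inactive there by construction). This
#' is a deliberately additive potential: no many-body cooperativity term is
#' included, so its barrier heights are not comparable to nonadditive
#' structure-based models.
#'
#' @param conf a [Conformation-class].
#' @param native a [NativeReference-class] of the same size.
#' @param p [GoModelParams-class].
#' @return list with `energy` (kT) and `gradient` (n x 3, kT/Angstrom).
#' @export
goEnergy <- function(conf, native, p = goModelParams()) {
  if (nResidues(conf) != nResidues(native))
    stop("conformation and native differ in residue count")
  top <- .goTopology(native, p)
  cppGoEnergy(conf@coords, top$bi, top$bj, top$br0, top$ci, top$cj, top$cr0,
              top$ei, top$ej, p@bondK, p@contactDepth, p@contactWidth,
              p@excludedRadius, p@excludedK)
}

# shared driver: seeded C++ integration returning the raw kernel output
.langevinRaw <- function(start, native, p, nsteps, stride, seed, bias,
                         temperature, params) {
  top <- .goTopology(native, p, params)
  kT <- temperature / p@tempRef
  biasCenter <- if (is.null(bias)) 0 else bias[[1L]]
  biasK <- if (is.null(bias)) 0 else bias[[2L]]
  .seedGuard(seed,
    cppLangevin(start@coords, top$bi, top$bj, top$br0, top$ci, top$cj,
                top$cr0, top$ei, top$ej, top$qi, top$qj, top$qr0, top$q2s2,
                p@bondK, p@contactDepth, p@contactWidth, p@excludedRadius,
                p@excludedK, kT, p@dt, p@gamma, as.integer(nsteps),
                as.integer(stride), biasCenter, biasK, 1e10))
}

.rawFrames <- function(raw, n) {
  nf <- raw$recorded
  arr <- array(raw$frames[seq_len(3L * n * nf)], dim = c(3L, n, nf))
  lapply(seq_len(nf), function(r) conformation(t(arr[, , r])))
}

#' Overdamped Langevin run on the Go landscape
#'
#' Euler-Maruyama integration of the additive Go potential, optionally with
#' a harmonic umbrella bias (kSpring/2)(Q_w - center)^2 whose analytic
#' gradient is propagated through the internal-distance similarity. Frames
#' are recorded every `stride` steps with their Go energy, Q_w and Q_o.
#' Runs are reproducible for a given seed. Temperature enters in reduced
#' units: kT = temperature / tempRef.
#'
#' @param start starting [Conformation-class].
#' @param native a [NativeReference-class].
#' @param p [GoModelParams-class]; `dt` must respect the stability bound.
#' @param nsteps integration steps.
#' @param stride recording interval (default 50).
#' @param seed integer seed.
#' @param bias optional c(center, kSpring) on Q_w.
#' @param temperature K (default the reference temperature, kT = 1).
#' @param params [MetricParams-class] defining Q_w and Q_o.
#' @return A [SimRun-class].
#' @export
langevinRun <- function(start, native, p = goModelParams(), nsteps = 10000L,
                        stride = 50L, seed = 1L, bias = NULL,
                        temperature = p@tempRef, params = metricParams()) {
  raw <- .langevinRaw(start, native, p, nsteps, stride, seed, bias,
                      temperature, params)
  if (raw$aborted)
    stop("energy diverged after ", raw$stepsDone,
         " steps (|E| > 1e10); reduce dt or the bias strength")
  frames <- .rawFrames(raw, nResidues(native))
  ens <- ensemble(frames)
  qo <- vapply(frames, fractionNativeContacts, numeric(1),
               contacts = native@contacts, params = params)
  ens@scalars <- data.frame(frame = seq_along(frames),
                            energy = raw$energy[seq_along(frames)],
                            qw = raw$qw[seq_along(frames)], qo = qo)
  new("SimRun", ensemble = ens, seed = as.integer(seed),
      bias = if (is.null(bias)) numeric(0) else as.numeric(bias),
      temperature = temperature)
}

#' Umbrella-sampling scan over Q_w
#'
#' One biased Langevin run per window center, each initialized from the
#' previous window's final frame (the first from the native structure), with
#' the first `discard` fraction of each window's recorded samples dropped as
#' equilibration. Centers are processed in the order given; passing them
#' from high to low Q_w lets each window start from an already adapted
#' structure.
#'
#' @param native a [NativeReference-class].
#' @param p [GoModelParams-class].
#' @param centers bias centers on Q_w.
#' @param kSpring bias strength, kT per Q_w unit^2 (default 1000).
#' @param nsteps steps per window.
#' @param stride recording interval (default 50).
#' @param seed integer seed (each window uses seed + window index).
#' @param temperature K.
#' @param discard equilibration fraction dropped per window (default 0.1).
#' @param params [MetricParams-class].
#' @return list of [UmbrellaWindow-class] with Q_w samples, in input order.
#' @export
umbrellaScan <- function(native, p = goModelParams(), centers,
                         kSpring = 1000, nsteps = 20000L, stride = 50L,
                         seed = 1L, temperature = p@tempRef, discard = 0.1,
                         params = metricParams()) {
  windows <- vector("list", length(centers))
  start <- native@native
  for (w in seq_along(centers)) {
    raw <- tryCatch(
      .langevinRaw(start, native, p, nsteps, stride, seed + w,
                   bias = c(centers[w], kSpring), temperature, params),
      error = function(e) stop("window ", w, " (center ", centers[w],
                               "): ", conditionMessage(e), call. = FALSE))
    if (raw$aborted)
      stop("window ", w, " (center ", centers[w], "): energy diverged")
    qwSamples <- raw$qw[seq_len(raw$recorded)]
    keep <- qwSamples[seq.int(floor(discard * length(qwSamples)) + 1L,
                              length(qwSamples))]
    windows[[w]] <- umbrellaWindow(centers[w], kSpring, keep, temperature)
    start <- conformation(raw$final)
  }
  windows
}

#' Melting scan of the toy model
#'
#' Unbiased simulation over an ascending temperature ladder. In chained
#' mode each temperature starts from the previous one's final frame
#' (emulating a continuous heating run, so the system is pre-equilibrated
#' near each new temperature); otherwise every temperature restarts from
#' the native structure, which makes the temperatures statistically
#' independent — the per-point noise then averages down faster over
#' replicas, at the cost of a folded-start relaxation bias near the
#' transition that is systematic rather than random. The mean Q_w of the
#' second half of each run (the first half is discarded as equilibration),
#' averaged over independent replicas, gives the melting-curve input for
#' [meltingCurve()].
#'
#' @param native a [NativeReference-class].
#' @param p [GoModelParams-class].
#' @param temperatures K, ascending ladder.
#' @param nsteps steps per temperature.
#' @param stride recording interval.
#' @param seed integer seed.
#' @param nReplicas independent heating runs averaged (default 2).
#' @param chained start each temperature from the previous final frame
#'   (default) instead of from the native structure.
#' @param params [MetricParams-class].
#' @return data.frame with columns `temperature`, `meanQw`.
#' @export
meltScan <- function(native, p = goModelParams(),
                     temperatures = seq(100, 650, by = 50),
                     nsteps = 50000L, stride = 50L, seed = 1L,
                     nReplicas = 2L, chained = TRUE,
                     params = metricParams()) {
  acc <- matrix(0, length(temperatures), nReplicas)
  for (rep in seq_len(nReplicas)) {
    start <- native@native
    for (k in seq_along(temperatures)) {
      raw <- .langevinRaw(start, native, p, nsteps, stride,
                          seed + 997L * rep + 7L * k, bias = NULL,
                          temperatures[k], params)
      if (raw$aborted) stop("melting run at ", temperatures[k], " K diverged")
      s <- raw$qw[seq_len(raw$recorded)]
      acc[k, rep] <- mean(s[seq.int(floor(length(s) / 2) + 1L, length(s))])
      if (chained) start <- conformation(raw$final)
    }
  }
  data.frame(temperature = temperatures, meanQw = rowMeans(acc))
}

# ---------------------------------------------------------------------------
# 1D Brownian sampler (WHAM oracle support)
# ---------------------------------------------------------------------------

#' Analytic 1D potentials
#'
#' Constructors for the named analytic forms consumed by [brownian1d()]:
#' a harmonic well kappa/2 (x - x0)^2 and a symmetric double well
#' 16 h x^2 (1 - x)^2 with minima at 0 and 1 and barrier height h at
#' x = 1/2 (potential-energy height; the free-energy barrier follows from
#' Boltzmann-integrating exp(-V) per bin).
#'
#' @param kappa harmonic stiffness (kT per unit^2).
#' @param x0 harmonic center.
#' @return list with functions `f(x)` and `grad(x)` and a `name`.
#' @export
harmonicPotential <- function(kappa = 1, x0 = 0) {
  list(f = function(x) kappa / 2 * (x - x0)^2,
       grad = function(x) kappa * (x - x0),
       name = "harmonic")
}

#' @param height barrier height h in kT.
#' @rdname harmonicPotential
#' @export
doubleWellPotential <- function(height = 4) {
  list(f = function(x) 16 * height * x^2 * (1 - x)^2,
       grad = function(x) 16 * height * (2 * x * (1 - x)^2 -
                                         2 * x^2 * (1 - x)),
       name = "double-well")
}

#' 1D overdamped Brownian sampler under umbrella windows
#'
#' Euler-Maruyama sampling of a differentiable 1D potential, one window per
#' row of `windows`, each started at its bias center. Used to validate the
#' WHAM machinery against analytic free energies.
#'
#' @param potential list with `f` and `grad` ([harmonicPotential()],
#'   [doubleWellPotential()], or user-supplied).
#' @param windows data.frame with columns `center` and `kSpring` (kT units).
#' @param nsteps steps per window.
#' @param seed integer seed.
#' @param dt integrator step (default 0.01).
#' @param kT thermal energy (default 1).
#' @param temperature nominal temperature tag, K (default 300).
#' @param burnin fraction of initial samples dropped (default 0).
#' @return list of [UmbrellaWindow-class].
#' @export
brownian1d <- function(potential, windows, nsteps = 20000L, seed = 1L,
                       dt = 0.01, kT = 1, temperature = 300, burnin = 0) {
  stopifnot(all(c("center", "kSpring") %in% names(windows)))
  out <- vector("list", nrow(windows))
  .seedGuard(seed, {
    for (w in seq_len(nrow(windows))) {
      cw <- windows$center[w]; kw <- windows$kSpring[w]
      x <- cw
      xs <- numeric(nsteps)
      noise <- sqrt(2 * kT * dt) * rnorm(nsteps)
      for (s in seq_len(nsteps)) {
        x <- x - dt * (potential$grad(x) + kw * (x - cw)) + noise[s]
        xs[s] <- x
      }
      keep <- xs[seq.int(floor(burnin * nsteps) + 1L, nsteps)]
      out[[w]] <- umbrellaWindow(cw, kw, keep, temperature)
    }
  })
  out
}
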