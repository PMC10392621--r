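# bin samples onto a fixed grid; returns integer bin index or NA outside
.binIndex <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

#' Free-energy profile by histogram inversion
#'
#' Boltzmann inversion of a (weighted) histogram: F_b = -ln p_b in kT, with
#' the minimum over occupied bins pinned at zero. Weights need not be
#' normalized; scaling all weights leaves the profile unchanged. Unoccupied
#' bins are flagged, never interpolated.
#'
#' @param values reaction-coordinate samples.
#' @param weights optional per-sample weights (default uniform).
#' @param bins bin count (default 50).
#' @param range length-2 coordinate range (default the sample range).
#' @return A [FreeEnergyProfile-class].
#' @export
histogramFreeEnergy <- function(values, weights = NULL, bins = 50L,
                                range = base::range(values)) {
  if (diff(range) <= 0) stop("empty coordinate range")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values))
    stop("one weight per sample required")
  edges <- seq(range[1L], range[2L], length.out = bins + 1L)
  idx <- .binIndex(values, edges)
  if (all(is.na(idx))) stop("no samples inside the requested range")
  p <- numeric(bins)
  agg <- tapply(weights[!is.na(idx)], idx[!is.na(idx)], sum)
  p[as.integer(names(agg))] <- agg
  p <- p / sum(p)
  occ <- p > 0
  F <- rep(NA_real_, bins)
  F[occ] <- -log(p[occ])
  F[occ] <- F[occ] - min(F[occ])
  new("FreeEnergyProfile", binCenters = (edges[-1L] + edges[-(bins + 1L)]) / 2,
      freeEnergy = F, occupied = occ)
}

#' Combine umbrella windows with WHAM
#'
#' Standard single-temperature self-consistent weighted histogram analysis
#' over binned counts, with the harmonic bias (kSpring/2)(xi - center)^2
#' recomputed from each window's metadata (energies in kT). Iterates the
#' window free energies f_i to convergence (max |Delta f_i| < tol, gauge
#' f_1 = 0) and returns the unbiased profile renormalized to minimum 0,
#' together with per-sample unbiased weights for re-histogramming the same
#' frames over a different coordinate.
#'
#' @param windows list of [UmbrellaWindow-class] sharing one temperature.
#' @param bins bin count (default 50).
#' @param range coordinate range (default the pooled sample range).
#' @param tol convergence tolerance on the window free energies
#'   (default 1e-7).
#' @param maxIter maximum iterations (default 1e5).
#' @return list with `profile` (a [FreeEnergyProfile-class]), `f` (window
#'   free energies, f_1 = 0), `sampleWeights` (per window, unbiased,
#'   normalized over the pooled samples), `iterations`.
#' @export
wham <- function(windows, bins = 50L, range = NULL, tol = 1e-7,
                 maxIter = 1e5L) {
  if (length(windows) < 1L) stop("need at least one window")
  temps <- vapply(windows, function(w) w@temperature, numeric(1))
  if (diff(base::range(temps)) > 1e-9)
    stop("single-temperature WHAM: all windows must share one temperature")
  pooled <- unlist(lapply(windows, function(w) w@samples))
  if (is.null(range)) range <- base::range(pooled)
  if (diff(range) <= 0) stop("empty coordinate range")
  edges <- seq(range[1L], range[2L], length.out = bins + 1L)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  W <- length(windows)
  counts <- matrix(0, W, bins)         # n_ib
  for (i in seq_len(W)) {
    idx <- .binIndex(windows[[i]]@samples, edges)
    tab <- table(idx[!is.na(idx)])
    counts[i, as.integer(names(tab))] <- as.numeric(tab)
  }
  Ntot <- rowSums(counts)
  if (any(Ntot == 0))
    stop("window(s) ", paste(which(Ntot == 0), collapse = ", "),
         " have no samples inside the range")
  # histogram-overlap connectivity check
  occ <- counts > 0
  compOf <- seq_len(W)
  repeat {
    changed <- FALSE
    for (i in seq_len(W)) for (j in seq_len(W)) {
      if (compOf[i] != compOf[j] && any(occ[i, ] & occ[j, ])) {
        compOf[compOf == max(compOf[c(i, j)])] <- min(compOf[c(i, j)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(compOf)) > 1L)
    warning("umbrella windows do not all overlap; disconnected segments: ",
            paste(vapply(split(seq_len(W), compOf),
                         function(g) paste(g, collapse = "+"), character(1)),
                  collapse = " | "))
  # bias energy of window i evaluated at bin center b (kT)
  bias <- t(vapply(windows,
                   function(w) w@kSpring / 2 * (centers - w@center)^2,
                   numeric(bins)))
  nb <- colSums(counts)
  f <- numeric(W)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(Ntot * exp(f - bias))           # bins
    p <- ifelse(denom > 0, nb / denom, 0)
    fNew <- -log(pmax(rowSums(exp(-bias) %*% diag(p, bins)), .Machine$double.xmin))
    fNew <- fNew - fNew[1L]
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) break
    if (iter >= maxIter)
      stop("WHAM failed to converge in ", maxIter,
           " iterations (residual ", signif(delta, 3), ")")
  }
  p <- p / sum(p)
  occB <- nb > 0
  F <- rep(NA_real_, bins)
  F[occB] <- -log(p[occB])
  F[occB] <- F[occB] - min(F[occB])
  profile <- new("FreeEnergyProfile", binCenters = centers,
                 freeEnergy = F, occupied = occB)
  # per-sample unbiased weights: w_s = 1 / sum_i N_i exp(f_i - u_i(x_s))
  sw <- lapply(windows, function(w) {
    u <- vapply(windows, function(wi) wi@kSpring / 2 *
                  (w@samples - wi@center)^2, numeric(length(w@samples)))
    1 / rowSums(sweep(exp(-u), 2L, Ntot * exp(f), "*"))
  })
  tot <- sum(unlist(sw))
  sw <- lapply(sw, function(x) x / tot)
  list(profile = profile, f = f, sampleWeights = sw, iterations = iter)
}

#' Melting curve and folding-temperature estimate
#'
#' Builds the mean global reaction coordinate versus temperature and
#' estimates the folding temperature T_F as the temperature at which a
#' fitted monotone 4-parameter logistic crosses the midpoint between its
#' folded and unfolded plateaus, falling back to linear interpolation of the
#' midpoint crossing if the fit fails. The curve must show unfolding (mean
#' coordinate decreasing overall with temperature).
#'
#' @param runs either a data.frame with columns `temperature` (K) and
#'   `meanQw` (one row per temperature), or a list of [SimRun-class] objects
#'   whose per-frame Q_w is averaged per run.
#' @return A [MeltingCurve-class].
#' @export
meltingCurve <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs) &&
      all(vapply(runs, is, logical(1), "SimRun"))) {
    runs <- data.frame(
      temperature = vapply(runs, function(r) r@temperature, numeric(1)),
      meanQw = vapply(runs, function(r) mean(r@ensemble@scalars$qw),
                      numeric(1)))
  }
  runs <- runs[order(runs$temperature), , drop = FALSE]
  tt <- runs$temperature
  y <- runs$meanQw
  if (length(tt) < 4L) stop("need at least 4 temperatures across the transition")
  if (y[length(y)] >= y[1L])
    stop("mean coordinate does not decrease with temperature: no unfolding ",
         "transition to locate")
  yF <- max(y); yU <- min(y)
  span <- diff(base::range(tt))
  # midpoint crossing of the isotonic (monotone non-increasing) smooth:
  # the fallback estimate and the sanity anchor for the fit
  ys <- -stats::isoreg(tt, -y)$yf
  mid <- (max(ys) + min(ys)) / 2
  k <- which(ys[-length(ys)] >= mid & ys[-1L] < mid)[1L]
  if (is.na(k)) stop("could not locate a midpoint crossing")
  tfInterp <- tt[k] + (tt[k + 1L] - tt[k]) * (ys[k] - mid) / (ys[k] - ys[k + 1L])
  mid0 <- tt[which.min(abs(y - mid))]
  # bounded 4-parameter logistic: plateaus near the observed extremes and a
  # finite width, so the fit stays identified even for broad transitions
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ yu + (yf - yu) / (1 + exp((tt - t0) / w)),
                      start = list(yf = yF, yu = yU, t0 = mid0,
                                   w = span / 10),
                      lower = c(yf = yF - 0.1, yu = 0, t0 = min(tt),
                                w = span / 100),
                      upper = c(yf = 1, yu = yU + 0.1, t0 = max(tt),
                                w = span / 3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit)
  if (ok) {
    cf <- stats::coef(fit)
    ok <- is.finite(cf[["t0"]]) && cf[["yf"]] > cf[["yu"]] &&
      abs(cf[["t0"]] - tfInterp) <= 0.05 * span
  }
  if (ok) {
    tf <- unname(cf[["t0"]])
    method <- "logistic"
  } else {
    tf <- tfInterp
    method <- "interpolation"
  }
  new("MeltingCurve", temperatures = tt, meanCoord = pmin(pmax(y, 0), 1),
      tF = tf, method = method)
}
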