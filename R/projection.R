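#' Reduce an ensemble to representative conformations
#'
#' Leader clustering in frame order: each frame joins the first existing
#' representative whose dissimilarity is at most `cutoff`, otherwise it
#' becomes a new representative. A cutoff of exactly 0 is the identity map
#' (clustering off).
#'
#' @param delta a [DissimilarityMatrix-class].
#' @param cutoff dissimilarity threshold, 0 <= cutoff < 1.
#' @return list with `representatives` (frame indices of representatives)
#'   and `repOf` (frame -> representative index map).
#' @export
reduceRepresentatives <- function(delta, cutoff = 0) {
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must satisfy 0 <= cutoff < 1")
  v <- delta@values
  m <- nrow(v)
  if (cutoff == 0)
    return(list(representatives = seq_len(m), repOf = seq_len(m)))
  reps <- integer(0)
  repOf <- integer(m)
  for (k in seq_len(m)) {
    hit <- if (length(reps)) which(v[k, reps] <= cutoff)[1L] else NA_integer_
    if (is.na(hit)) {
      reps <- c(reps, k)
      repOf[k] <- length(reps)
    } else repOf[k] <- hit
  }
  list(representatives = reps, repOf = repOf)
}

# one majorization (SMACOF/Guttman) descent from a given start; the C++
# kernel separates coincident points by a minimal jitter from the seeded
# RNG stream
.smacofRun <- function(v, X, maxIter, tol) {
  run <- cppSmacof(v, X, as.integer(maxIter), tol)
  list(X = run$X, stress = run$trace[length(run$trace)], trace = run$trace,
       iterations = run$iterations)
}

#' Embed a dissimilarity matrix in 2D by stress majorization
#'
#' Computes 2D coordinates minimizing the normalized squared stress
#' \deqn{S = \sum_{k<l} (\delta_{kl} - d_{kl})^2 \Big/ \sum_{k<l}
#' \delta_{kl}^2} by iterative majorization (the Guttman transform), which
#' guarantees a non-increasing stress at every iteration — the reason this
#' form is preferred over raw absolute deviation, which is reported as a
#' diagnostic (`stressAbs`). Initial coordinates are seeded pseudo-random
#' placements in the unit square; the best of `nStarts` starts is kept.
#' Output is reproducible bit-for-bit for a given seed; axis orientation and
#' reflection are arbitrary.
#'
#' @param delta a [DissimilarityMatrix-class] (n >= 2).
#' @param dim embedding dimension; only 2 is supported.
#' @param seed integer seed (default 0).
#' @param maxIter maximum majorization iterations per start (default 1000).
#' @param tol stop when the stress decrease falls below this (default 1e-8).
#' @param nStarts number of seeded restarts (default 4).
#' @return A [Projection-class] with identity frame map.
#' @export
embedDissimilarity <- function(delta, dim = 2L, seed = 0L, maxIter = 1000L,
                               tol = 1e-8, nStarts = 4L) {
  if (dim != 2L) stop("only 2D embedding is supported")
  v <- delta@values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 conformations to embed")
  idn <- seq_len(n)
  if (all(v == 0)) {
    warning("all dissimilarities are zero; returning coincident points")
    return(new("Projection", coords = matrix(0, n, 2L), repOf = idn,
               representatives = idn, stress = 0, stressAbs = 0,
               stressTrace = 0, seed = as.integer(seed), iterationsRun = 0L))
  }
  if (n == 2L) {
    X <- rbind(c(0, 0), c(v[1L, 2L], 0))
    return(new("Projection", coords = X, repOf = idn, representatives = idn,
               stress = 0, stressAbs = 0, stressTrace = 0,
               seed = as.integer(seed), iterationsRun = 0L))
  }
  best <- NULL
  .seedGuard(seed, {
    for (s in seq_len(nStarts)) {
      X0 <- matrix(runif(2L * n), n, 2L)
      run <- .smacofRun(v, X0, maxIter, tol)
      if (is.null(best) || run$stress < best$stress) best <- run
    }
  })
  d <- as.matrix(dist(best$X))
  sAbs <- mean(abs(v[upper.tri(v)] - d[upper.tri(d)]))
  new("Projection", coords = unname(best$X), repOf = idn,
      representatives = idn, stress = best$stress, stressAbs = sAbs,
      stressTrace = best$trace, seed = as.integer(seed),
      iterationsRun = best$iterations)
}

#' Project an ensemble into an effective 2D phase space
#'
#' The full visualisation pipeline: pairwise dissimilarities
#' ([dissimilarityMatrix()]), optional leader-clustering reduction to
#' representatives ([reduceRepresentatives()]), and stress-majorization
#' embedding of the representative dissimilarities
#' ([embedDissimilarity()]).
#'
#' @param ens an [Ensemble-class] or a precomputed
#'   [DissimilarityMatrix-class].
#' @param params [MetricParams-class] (ignored when `ens` is already a
#'   dissimilarity matrix).
#' @param cutoff representative-clustering dissimilarity threshold
#'   (default 0 = off).
#' @param seed,maxIter,tol,nStarts passed to [embedDissimilarity()].
#' @return A [Projection-class]; `repOf` maps every input frame to its
#'   representative's row in the coordinates.
#' @export
elvim <- function(ens, params = metricParams(), cutoff = 0, seed = 0L,
                  maxIter = 1000L, tol = 1e-8, nStarts = 4L) {
  delta <- if (is(ens, "DissimilarityMatrix")) ens
           else dissimilarityMatrix(ens, params)
  red <- reduceRepresentatives(delta, cutoff)
  sub <- dissimilarity(delta@values[red$representatives,
                                    red$representatives, drop = FALSE])
  proj <- embedDissimilarity(sub, seed = seed, maxIter = maxIter, tol = tol,
                             nStarts = nStarts)
  new("Projection", coords = proj@coords, repOf = as.integer(red$repOf),
      representatives = as.integer(red$representatives),
      stress = proj@stress, stressAbs = proj@stressAbs,
      stressTrace = proj@stressTrace, seed = proj@seed,
      iterationsRun = proj@iterationsRun)
}

#' Attach a reaction-coordinate axis to a 2D projection
#'
#' Builds a 3D representation whose (x, y) are exactly the source projection
#' and whose z is a reaction coordinate (typically Q_o). `zValues` may be
#' given per representative, or per frame, in which case each
#' representative's z is the mean over its member frames.
#'
#' @param proj a [Projection-class].
#' @param zValues numeric; length = number of representatives (direct) or
#'   number of frames (aggregated by mean).
#' @return An [Augmented3D-class].
#' @export
augmentReactionAxis <- function(proj, zValues) {
  nRep <- nrow(proj@coords)
  nFr <- length(proj@repOf)
  if (length(zValues) == nRep) {
    z <- as.numeric(zValues)
  } else if (length(zValues) == nFr) {
    z <- as.numeric(tapply(zValues, proj@repOf, mean)[as.character(seq_len(nRep))])
  } else {
    stop("zValues must have one entry per representative (", nRep,
         ") or per frame (", nFr, "), got ", length(zValues))
  }
  new("Augmented3D", coords3 = cbind(proj@coords, z, deparse.level = 0))
}

#' @param x a Projection
#' @param ... passed to [graphics::plot()]
#' @describeIn Projection-class scatter plot of the 2D embedding
#' @export
setMethod("plot", signature(x = "Projection", y = "missing"),
  function(x, ...) {
    graphics::plot(x@coords[, 1L], x@coords[, 2L], xlab = "x", ylab = "y",
                   asp = 1, ...)
  })
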