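#' Internal-distance similarity between two conformations
#'
#' The Gaussian internal-distance similarity
#' \deqn{q = \frac{1}{N_p} \sum_{(i,j)} \exp\!\left[-\frac{(r_{ij}^a -
#'   r_{ij}^b)^2}{2\,\sigma_{ij}^2}\right], \qquad
#'   \sigma_{ij} = \sigma_0 |i-j|^{\epsilon},}
#' summed over all residue pairs with \eqn{|i-j| \ge} `minSepQ` (default 3,
#' excluding trivially rigid bonded neighbours), or over an explicit pair
#' subset. q is unitless, lies in (0, 1], equals 1 iff the two conformations
#' share all qualifying internal distances, and is invariant under rigid
#' motion of either conformation.
#'
#' @param a,b [Conformation-class] objects with equal residue counts.
#' @param params [MetricParams-class].
#' @param pairSubset optional 2-column matrix of residue pairs (i < j), each
#'   obeying the `minSepQ` separation rule.
#' @return unitless scalar in (0, 1].
#' @examples
#' chain <- conformation(cbind(3.8 * (0:4), 0, 0))
#' pairSimilarity(chain, chain)  # 1
#' @export
pairSimilarity <- function(a, b, params = metricParams(), pairSubset = NULL) {
  if (nResidues(a) != nResidues(b))
    stop("conformations differ in residue count (", nResidues(a), " vs ",
         nResidues(b), ")")
  pairs <- .resolvePairs(nResidues(a), params, pairSubset)
  da <- .pairDistances(a@coords, pairs[, 1L], pairs[, 2L])
  db <- .pairDistances(b@coords, pairs[, 1L], pairs[, 2L])
  mean(exp(-(da - db)^2 / (2 * .sigma2(pairs, params))))
}

.resolvePairs <- function(n, params, pairSubset = NULL) {
  if (is.null(pairSubset)) {
    pairs <- .qualifyingPairs(n, params@minSepQ)
    if (nrow(pairs) == 0L)
      stop("no qualifying pairs: chain too short for minSepQ = ",
           params@minSepQ)
    return(pairs)
  }
  pairSubset <- as.matrix(pairSubset)
  storage.mode(pairSubset) <- "integer"
  if (nrow(pairSubset) == 0L) stop("pair subset is empty")
  if (any(pairSubset[, 2L] - pairSubset[, 1L] < params@minSepQ))
    stop("pair subset violates the minimum separation rule (minSepQ = ",
         params@minSepQ, ")")
  pairSubset
}

#' Global reaction coordinate Q_w
#'
#' The internal-distance similarity ([pairSimilarity()]) between a
#' conformation and the native reference over the full qualifying pair set.
#'
#' @param conf a [Conformation-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @return unitless scalar in (0, 1].
#' @export
qw <- function(conf, native, params = metricParams()) {
  pairSimilarity(conf, native@native, params)
}

#' Local internal-distance similarity
#'
#' The q similarity restricted to pairs with at least one member in the
#' focus residue set (a single residue index or a repeat's residue range).
#' Interface pairs are included; pass an explicit `pairSubset` to
#' [pairSimilarity()] for an internal-only variant. Residue sets with no
#' qualifying pair yield `NA` (undefined), never 0.
#'
#' @param conf a [Conformation-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @param focus residue index or vector of residue indices (e.g. one repeat).
#' @return unitless scalar in (0, 1], or `NA` if no pair qualifies.
#' @export
localQ <- function(conf, native, params = metricParams(), focus) {
  n <- nResidues(conf)
  if (any(focus < 1L) || any(focus > n)) stop("focus indices out of range")
  pairs <- .qualifyingPairs(n, params@minSepQ)
  keep <- pairs[, 1L] %in% focus | pairs[, 2L] %in% focus
  if (!any(keep)) return(NA_real_)
  pairSimilarity(conf, native@native, params,
                 pairSubset = pairs[keep, , drop = FALSE])
}

#' Pairwise dissimilarity matrix of an ensemble
#'
#' delta_kl = 1 - q_kl over every unordered pair of frames, computed once per
#' pair; no native reference is involved. The result is symmetric with zero
#' diagonal and entries in \eqn{[0, 1]}; the triangle inequality is not guaranteed.
#'
#' @param ens an [Ensemble-class] with >= 2 frames.
#' @param params [MetricParams-class].
#' @return A [DissimilarityMatrix-class].
#' @export
dissimilarityMatrix <- function(ens, params = metricParams()) {
  m <- nFrames(ens)
  if (m < 2L) stop("need at least 2 frames")
  pairs <- .qualifyingPairs(nResidues(ens), params@minSepQ)
  if (nrow(pairs) == 0L)
    stop("no qualifying pairs for frames of ", nResidues(ens), " residues")
  s2 <- 2 * .sigma2(pairs, params)
  D <- .ensemblePairDistances(ens, pairs)
  delta <- matrix(0, m, m)
  for (k in seq_len(m - 1L)) {
    rest <- (k + 1L):m
    diff2 <- sweep(D[rest, , drop = FALSE], 2L, D[k, ])^2
    q <- rowMeans(exp(-sweep(diff2, 2L, s2, "/")))
    delta[k, rest] <- 1 - q
    delta[rest, k] <- 1 - q
  }
  delta[delta < 0] <- 0
  dissimilarity(delta)
}

#' Fraction of native contacts Q_o
#'
#' The smoothed fraction of native contacts
#' \deqn{Q_o = \frac{1}{N_S} \sum_{(i,j) \in S}
#'   \frac{1}{1 + \exp[\beta^0 (r_{ij} - \lambda r_{ij}^0)]},}
#' with the contact set S built from the native structure
#' ([buildContactSet()]), smoothing \eqn{\beta^0} (printed in nm^-1) and the
#' dimensionless fluctuation allowance \eqn{\lambda}. Strictly in (0, 1) and
#' strictly decreasing in every contact distance.
#'
#' @param conf a [Conformation-class].
#' @param contacts a [ContactSet-class] (or [NativeReference-class], whose
#'   contact set is used).
#' @param params [MetricParams-class].
#' @return unitless scalar in (0, 1).
#' @export
fractionNativeContacts <- function(conf, contacts, params = metricParams()) {
  if (is(contacts, "NativeReference")) contacts <- contacts@contacts
  d <- .pairDistances(conf@coords, contacts@pairs[, 1L], contacts@pairs[, 2L])
  mean(1 / (1 + exp(.betaA(params) * (d - params@lam * contacts@nativeDist))))
}

#' Per-residue local fraction of native contacts
#'
#' For each residue, the Q_o logistic averaged over the native contacts that
#' contain it. Residues participating in no native contact are flagged
#' undefined (`NA`) rather than reported as 0.
#'
#' @inheritParams fractionNativeContacts
#' @return A [LocalQProfile-class] of kind "Qo_local".
#' @export
localFractionNativeContacts <- function(conf, contacts,
                                        params = metricParams()) {
  if (is(contacts, "NativeReference")) contacts <- contacts@contacts
  n <- nResidues(conf)
  d <- .pairDistances(conf@coords, contacts@pairs[, 1L], contacts@pairs[, 2L])
  term <- 1 / (1 + exp(.betaA(params) *
                       (d - params@lam * contacts@nativeDist)))
  sums <- counts <- numeric(n)
  for (col in 1:2) {
    agg <- tapply(term, contacts@pairs[, col], sum)
    idx <- as.integer(names(agg))
    sums[idx] <- sums[idx] + agg
    cnt <- tabulate(contacts@pairs[, col], nbins = n)
    counts <- counts + cnt
  }
  vals <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  new("LocalQProfile", perResidue = vals, coordinateKind = "Qo_local")
}

#' Mean contact map of a set of frames
#'
#' For every residue pair more than three residues apart, the fraction of
#' frames in which the pair is closer than the contact cutoff. This is a
#' hard-cutoff occupancy (used for mean contact maps of selected regions),
#' not the smoothed Q_o kernel.
#'
#' @param frames an [Ensemble-class], a list of [Conformation-class], or a
#'   single [Conformation-class].
#' @param params [MetricParams-class].
#' @return data.frame with columns `i`, `j`, `prob`.
#' @export
contactMap <- function(frames, params = metricParams()) {
  if (is(frames, "Conformation")) frames <- list(frames)
  if (is(frames, "Ensemble")) frames <- frames@frames
  if (length(frames) < 1L) stop("need at least one frame")
  n <- nResidues(frames[[1L]])
  pairs <- .qualifyingPairs(n, 4L)
  cut <- .cutoffA(params)
  hits <- numeric(nrow(pairs))
  for (f in frames)
    hits <- hits + (.pairDistances(f@coords, pairs[, 1L], pairs[, 2L]) < cut)
  data.frame(i = pairs[, 1L], j = pairs[, 2L], prob = hits / length(frames))
}

#' Radius of gyration
#'
#' Root mean squared distance of the C-alpha positions to their centroid,
#' with equal residue masses.
#'
#' @param conf a [Conformation-class] or a raw n x 3 coordinate matrix.
#' @return Angstrom.
#' @export
radiusOfGyration <- function(conf) {
  x <- if (is(conf, "Conformation")) conf@coords else as.matrix(conf)
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2L, ctr)^2)))
}

#' Per-frame reaction-coordinate table
#'
#' Convenience wrapper computing, for every frame of an ensemble, the global
#' coordinates Q_w, Q_o and Rg, plus per-repeat local q and local Q_o.
#'
#' @param ens an [Ensemble-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @return data.frame with one row per frame.
#' @export
ensembleMetrics <- function(ens, native, params = metricParams()) {
  pairs <- .qualifyingPairs(nResidues(ens), params@minSepQ)
  s2 <- .sigma2(pairs, params)
  d0 <- .pairDistances(native@native@coords, pairs[, 1L], pairs[, 2L])
  G <- .pairTerms(.ensemblePairDistances(ens, pairs), d0, s2)
  Tm <- .contactTerms(ens, native@contacts, params)
  out <- data.frame(frame = seq_len(nFrames(ens)),
                    Qw = rowMeans(G), Qo = rowMeans(Tm),
                    Rg = vapply(ens@frames, radiusOfGyration, numeric(1)))
  reps <- .repeatMembers(native)
  for (r in seq_along(reps)) {
    inQ <- pairs[, 1L] %in% reps[[r]] | pairs[, 2L] %in% reps[[r]]
    inC <- native@contacts@pairs[, 1L] %in% reps[[r]] |
           native@contacts@pairs[, 2L] %in% reps[[r]]
    out[[paste0("q_R", r)]] <- rowMeans(G[, inQ, drop = FALSE])
    out[[paste0("Qo_R", r)]] <- rowMeans(Tm[, inC, drop = FALSE])
  }
  out
}
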