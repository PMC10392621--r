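# contact incidence matrix: contacts x residues
.contactIncidence <- function(contacts, n) {
  M <- matrix(0, nContacts(contacts), n)
  M[cbind(seq_len(nContacts(contacts)), contacts@pairs[, 1L])] <- 1
  M[cbind(seq_len(nContacts(contacts)), contacts@pairs[, 2L])] <- 1
  M
}

#' Residue-resolved folding heatmap
#'
#' For every frame computes the global Q_o and the per-residue local Q_o,
#' bins frames by global Q_o over the unit interval, and reports the per-bin mean of
#' each residue's local value. Residues in no native contact are undefined
#' throughout; empty bins are flagged missing.
#'
#' @param ens an [Ensemble-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @param nBins number of global-coordinate bins (default 20, >= 2).
#' @return A [FoldingHeatmap-class].
#' @export
foldingHeatmap <- function(ens, native, params = metricParams(),
                           nBins = 20L) {
  if (nBins < 2L) stop("need at least 2 bins")
  n <- nResidues(ens)
  Tm <- .contactTerms(ens, native@contacts, params)
  globalQ <- rowMeans(Tm)
  M <- .contactIncidence(native@contacts, n)
  perResidueCount <- colSums(M)
  localQ <- Tm %*% M
  localQ <- sweep(localQ, 2L, pmax(perResidueCount, 1), "/")
  localQ[, perResidueCount == 0] <- NA_real_
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- .binIndex(pmin(pmax(globalQ, 0), 1), edges)
  counts <- tabulate(bin, nbins = nBins)
  mat <- matrix(NA_real_, n, nBins)
  for (b in which(counts > 0))
    mat[, b] <- colMeans(localQ[bin == b, , drop = FALSE])
  new("FoldingHeatmap", binEdges = edges, matrix = mat,
      counts = as.integer(counts))
}

#' Detect apparent backtracking in a folding heatmap
#'
#' Flags residues whose bin-mean local Q_o decreases by at least `minDrop`
#' between occupied bins at least `minSpan` bins apart (inclusive) as the
#' global coordinate increases. Under 1D averaging such drops arise when
#' parallel folding routes place structurally different conformations at
#' the same global coordinate; they need not reflect real unfolding along
#' any single route.
#'
#' @param hm a [FoldingHeatmap-class] with at least `minSpan` + 1 occupied
#'   columns.
#' @param minDrop minimum decrease flagged (default 0.1).
#' @param minSpan minimum inclusive bin span of the decrease (default 2).
#' @param minCount minimum frames a bin needs before its mean enters the
#'   comparison (default 10): means over a handful of frames are noise, not
#'   estimates of the conditional average.
#' @return data.frame with columns `residue`, `binStart`, `binEnd`, `drop`
#'   (zero rows when nothing is flagged).
#' @export
detectBacktracking <- function(hm, minDrop = 0.1, minSpan = 2L,
                               minCount = 10L) {
  occ <- which(hm@counts >= pmax(minCount, 1L))
  if (length(occ) < minSpan + 1L)
    stop("need at least minSpan + 1 = ", minSpan + 1L,
         " occupied columns (got ", length(occ), ")")
  out <- list()
  for (res in seq_len(nrow(hm@matrix))) {
    v <- hm@matrix[res, occ]
    if (anyNA(v)) next
    best <- 0; bestA <- NA_integer_; bestB <- NA_integer_
    m <- length(v)
    for (a in seq_len(m - minSpan + 1L)) {
      bs <- seq.int(a + minSpan - 1L, m)
      drops <- v[a] - v[bs]
      k <- which.max(drops)
      if (drops[k] > best) { best <- drops[k]; bestA <- a; bestB <- bs[k] }
    }
    if (best >= minDrop)
      out[[length(out) + 1L]] <- data.frame(residue = res,
                                            binStart = occ[bestA],
                                            binEnd = occ[bestB],
                                            drop = best)
  }
  if (length(out) == 0L)
    return(data.frame(residue = integer(0), binStart = integer(0),
                      binEnd = integer(0), drop = numeric(0)))
  do.call(rbind, out)
}

# even-odd point-in-polygon; points on the boundary count as inside
.pointInPolygon <- function(pt, poly, eps = 1e-9) {
  nv <- nrow(poly)
  x <- pt[1L]; y <- pt[2L]
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # boundary test: distance from the segment
    vx <- xj - xi; vy <- yj - yi
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) max(0, min(1, ((x - xi) * vx + (y - yi) * vy) / L2)) else 0
    dx <- x - (xi + t * vx); dy <- y - (yi + t * vy)
    if (dx * dx + dy * dy <= eps^2) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < xi + (y - yi) * (xj - xi) / (yj - yi)) inside <- !inside
    j <- i
  }
  inside
}

#' Select projection frames inside a polygon
#'
#' Membership by the even-odd rule on the representatives' 2D positions
#' (boundary points count as inside); a frame belongs to the region when its
#' representative does, so the selection is reproducible from the stored
#' projection and polygon alone.
#'
#' @param proj a [Projection-class].
#' @param polygon 2D vertex matrix (>= 3 rows, simple polygon) in
#'   projection coordinates.
#' @return A [RegionSelection-class].
#' @export
selectRegion <- function(proj, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L)
    stop("polygon must be a matrix of >= 3 (x, y) vertices")
  inside <- vapply(seq_len(nrow(proj@coords)),
                   function(k) .pointInPolygon(proj@coords[k, ], polygon),
                   logical(1))
  if (!any(inside))
    stop("no representatives fall inside the polygon; adjust its vertices")
  reps <- which(inside)
  new("RegionSelection", polygon = polygon, representatives = reps,
      frames = which(proj@repOf %in% reps))
}

#' Mean contact map of a selected region
#'
#' [contactMap()] restricted to the member frames of a region selection.
#'
#' @param sel a [RegionSelection-class].
#' @param ens the [Ensemble-class] the projection was built from.
#' @param params [MetricParams-class].
#' @return data.frame with columns `i`, `j`, `prob`.
#' @export
regionContactMap <- function(sel, ens, params = metricParams()) {
  contactMap(ens@frames[sel@frames], params)
}

#' Assign frames to folding routes in a global-coordinate band
#'
#' For frames whose global Q_o lies inside the band, computes the
#' repeat-level local Q_o vector and assigns the nearest binary repeat-block
#' template: contiguous blocks of folded repeats anchored at the N terminus
#' ("N") or at the C terminus ("C"). Exact template ties are reported as
#' "ambiguous", never broken arbitrarily.
#'
#' @param ens an [Ensemble-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @param stageBand length-2 global-Q_o interval within the unit interval.
#' @return data.frame with columns `frame`, `qo`, `label` for the frames in
#'   the band.
#' @export
assignRoutes <- function(ens, native, params = metricParams(),
                         stageBand = c(0.25, 0.75)) {
  if (stageBand[1L] < 0 || stageBand[2L] > 1 || diff(stageBand) <= 0)
    stop("stageBand must be an interval within [0, 1]")
  R <- nRepeats(native)
  Tm <- .contactTerms(ens, native@contacts, params)
  globalQ <- rowMeans(Tm)
  sel <- which(globalQ >= stageBand[1L] & globalQ <= stageBand[2L])
  if (length(sel) == 0L) stop("no frames inside the global-Q band [",
                              stageBand[1L], ", ", stageBand[2L], "]")
  reps <- .repeatMembers(native)
  inRep <- vapply(reps, function(rr)
    native@contacts@pairs[, 1L] %in% rr | native@contacts@pairs[, 2L] %in% rr,
    logical(nContacts(native@contacts)))
  qRep <- sapply(seq_len(R), function(r)
    rowMeans(Tm[sel, inRep[, r], drop = FALSE]))
  qRep <- matrix(qRep, nrow = length(sel))
  # contiguous-block templates: prefix (N-anchored) and suffix (C-anchored)
  tmpl <- list(); lab <- character(0)
  for (k in seq_len(R - 1L)) {
    tmpl[[length(tmpl) + 1L]] <- as.numeric(seq_len(R) <= k); lab <- c(lab, "N")
    tmpl[[length(tmpl) + 1L]] <- as.numeric(seq_len(R) > R - k); lab <- c(lab, "C")
  }
  Tm2 <- do.call(rbind, tmpl)
  labels <- vapply(seq_along(sel), function(fi) {
    d2 <- rowSums(sweep(Tm2, 2L, qRep[fi, ])^2)
    best <- min(d2)
    hits <- unique(lab[d2 <= best + 1e-9])
    if (length(hits) > 1L) "ambiguous" else hits
  }, character(1))
  data.frame(frame = sel, qo = globalQ[sel], label = labels)
}

#' Commitment probability from seed conformations
#'
#' Runs unbiased Langevin replicas from each seed structure; a replica
#' succeeds when its recorded Q_o reaches the threshold at any frame within
#' the step budget. Returns the success fraction per seed group with a 95%
#' Clopper-Pearson interval; simulator aborts are counted separately and
#' excluded from the denominator.
#'
#' @param seeds a single [Conformation-class], a list of conformations (one
#'   group), or a named list of such lists (several groups). Replicas cycle
#'   over the structures within each group.
#' @param native a [NativeReference-class].
#' @param p [GoModelParams-class].
#' @param threshold Q_o success cutoff in (0, 1) (default 0.7, the
#'   conventional near-native value).
#' @param budget steps per replica.
#' @param nReplicas replicas per group (default 50).
#' @param seed integer seed.
#' @param temperature K.
#' @param stride recording interval (default 100).
#' @param params [MetricParams-class].
#' @return A [CommitmentResult-class], or a named list of them for several
#'   groups.
#' @export
commitment <- function(seeds, native, p = goModelParams(), threshold = 0.7,
                       budget = 20000L, nReplicas = 50L, seed = 1L,
                       temperature = p@tempRef, stride = 100L,
                       params = metricParams()) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (budget <= 0) stop("budget must be positive")
  if (is(seeds, "Conformation")) seeds <- list(seeds)
  groups <- if (all(vapply(seeds, is, logical(1), "Conformation")))
    list(group = seeds) else seeds
  results <- lapply(seq_along(groups), function(g) {
    grp <- groups[[g]]
    nFolded <- 0L; nDone <- 0L; nAborted <- 0L
    for (rep in seq_len(nReplicas)) {
      start <- grp[[(rep - 1L) %% length(grp) + 1L]]
      run <- tryCatch(
        langevinRun(start, native, p, nsteps = budget, stride = stride,
                    seed = seed + 10000L * g + rep,
                    temperature = temperature, params = params),
        error = function(e) NULL)
      if (is.null(run)) { nAborted <- nAborted + 1L; next }
      nDone <- nDone + 1L
      if (any(run@ensemble@scalars$qo >= threshold)) nFolded <- nFolded + 1L
    }
    if (nDone == 0L) stop("all replicas of group ", g, " aborted")
    frac <- nFolded / nDone
    ci <- c(if (nFolded == 0L) 0 else qbeta(0.025, nFolded, nDone - nFolded + 1),
            if (nFolded == nDone) 1 else qbeta(0.975, nFolded + 1, nDone - nFolded))
    new("CommitmentResult", nRuns = nDone, nFolded = nFolded,
        fraction = frac, ci = ci, threshold = threshold,
        budget = as.numeric(budget), nAborted = nAborted)
  })
  names(results) <- names(groups)
  if (length(results) == 1L) results[[1L]] else results
}

#' Terminal-fraying frequency per repeat
#'
#' Among frames whose global Q_w is at least `globalQMin` (the near-native
#' basin), the per-repeat frequency of the repeat-level local q falling
#' below `unfoldedCut` — the signature of repeats fraying off an otherwise
#' folded array.
#'
#' @param ens an [Ensemble-class].
#' @param native a [NativeReference-class].
#' @param params [MetricParams-class].
#' @param globalQMin Q_w cutoff selecting near-native frames, in (0, 1).
#' @param unfoldedCut local-q cutoff below which a repeat counts as frayed,
#'   in (0, 1).
#' @return named numeric vector, one frequency per repeat.
#' @export
frayingProfile <- function(ens, native, params = metricParams(),
                           globalQMin = 0.3, unfoldedCut = 0.5) {
  if (globalQMin <= 0 || globalQMin >= 1 || unfoldedCut <= 0 ||
      unfoldedCut >= 1) stop("cutoffs must lie in (0, 1)")
  pairs <- .qualifyingPairs(nResidues(ens), params@minSepQ)
  s2 <- .sigma2(pairs, params)
  d0 <- .pairDistances(native@native@coords, pairs[, 1L], pairs[, 2L])
  G <- .pairTerms(.ensemblePairDistances(ens, pairs), d0, s2)
  globalQ <- rowMeans(G)
  sel <- which(globalQ >= globalQMin)
  if (length(sel) == 0L)
    stop("no frames with global Q_w >= ", globalQMin)
  reps <- .repeatMembers(native)
  freqs <- vapply(seq_along(reps), function(r) {
    keep <- pairs[, 1L] %in% reps[[r]] | pairs[, 2L] %in% reps[[r]]
    localQ <- rowMeans(G[sel, keep, drop = FALSE])
    mean(localQ < unfoldedCut)
  }, numeric(1))
  names(freqs) <- paste0("R", seq_along(reps))
  freqs
}
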