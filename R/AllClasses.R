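#' @import methods
#' @importFrom stats dist rnorm runif setNames approx qbeta sd quantile
#' @importFrom utils write.table read.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib foldscape, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# Conformation
# ---------------------------------------------------------------------------

#' A single C-alpha conformation
#'
#' One frame of a coarse-grained trajectory: per-residue C-alpha positions in
#' Angstrom, ordered by sequence index, plus an optional model energy and
#' free-form metadata tags (window id, temperature, frame index, route label).
#'
#' @slot coords numeric matrix, n x 3, Angstrom.
#' @slot energy numeric scalar (model energy units) or `NA`.
#' @slot meta named list of metadata tags.
#' @export
setClass("Conformation",
  representation(coords = "matrix", energy = "numeric", meta = "list"),
  prototype(energy = NA_real_, meta = list()))

setValidity("Conformation", function(object) {
  x <- object@coords
  if (!is.numeric(x) || ncol(x) != 3L)
    return("coords must be a numeric n x 3 matrix")
  if (nrow(x) < 4L)
    return("a Conformation needs at least 4 residues")
  if (!all(is.finite(x)))
    return("all coordinates must be finite")
  if (length(object@energy) != 1L)
    return("energy must be a single value (possibly NA)")
  TRUE
})

#' Construct a Conformation
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param energy optional scalar energy.
#' @param meta optional named list of tags.
#' @return A [Conformation-class] object.
#' @examples
#' conf <- conformation(cbind(3.8 * (0:4), 0, 0))
#' nResidues(conf)
#' @export
conformation <- function(coords, energy = NA_real_, meta = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("Conformation", coords = coords, energy = as.numeric(energy)[1L],
      meta = meta)
}

#' @describeIn conformation number of residues
#' @param x,object a Conformation
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setMethod("nResidues", "Conformation", function(x) nrow(x@coords))

#' Coordinate accessor
#' @param x an object holding coordinates
#' @return a numeric matrix of coordinates (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Conformation", function(x) x@coords)

setMethod("show", "Conformation", function(object) {
  cat("Conformation:", nrow(object@coords), "residues")
  if (is.finite(object@energy)) cat(sprintf(", energy %.4g", object@energy))
  if (length(object@meta)) cat(" [", paste(names(object@meta), collapse = ", "), "]")
  cat("\n")
})

# ---------------------------------------------------------------------------
# Ensemble
# ---------------------------------------------------------------------------

#' An ordered ensemble of conformations
#'
#' @slot frames list of [Conformation-class], all with the same residue count.
#' @slot scalars optional per-frame data.frame (Q_w, Q_o, Rg, energy, labels);
#'   row count equals frame count when present.
#' @export
setClass("Ensemble",
  representation(frames = "list", scalars = "data.frame"),
  prototype(scalars = data.frame()))

setValidity("Ensemble", function(object) {
  if (length(object@frames) == 0L) return("ensemble must be non-empty")
  if (!all(vapply(object@frames, is, logical(1), "Conformation")))
    return("frames must all be Conformation objects")
  ns <- vapply(object@frames, nResidues, integer(1))
  if (length(unique(ns)) != 1L)
    return("all frames must share the same residue count")
  if (nrow(object@scalars) > 0L && nrow(object@scalars) != length(object@frames))
    return("scalar table row count must equal frame count")
  TRUE
})

#' Construct an Ensemble
#'
#' @param frames list of [Conformation-class] objects (uniform residue count).
#' @param scalars optional per-frame data.frame.
#' @return An [Ensemble-class].
#' @export
ensemble <- function(frames, scalars = NULL) {
  if (is.null(scalars)) scalars <- data.frame()
  new("Ensemble", frames = frames, scalars = scalars)
}

#' @describeIn ensemble number of frames
#' @param x an Ensemble
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "Ensemble", function(x) length(x@frames))

#' @export
setMethod("nResidues", "Ensemble", function(x) nResidues(x@frames[[1L]]))

#' Extract one frame or the frame list from an Ensemble
#' @param x an Ensemble
#' @param i frame index
#' @return `getFrame` a [Conformation-class]; `frames` the full list.
#' @export
getFrame <- function(x, i) x@frames[[i]]

#' @rdname getFrame
#' @export
frames <- function(x) x@frames

#' Per-frame scalar table of an Ensemble
#' @param x an Ensemble
#' @export
scalars <- function(x) x@scalars

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", length(object@frames), "frames x",
      nResidues(object), "residues\n")
  if (nrow(object@scalars))
    cat("  scalars:", paste(names(object@scalars), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ContactSet / NativeReference / MetricParams
# ---------------------------------------------------------------------------

#' Native contact set
#'
#' Residue pairs (i < j, |i - j| > 3) whose native C-alpha distance falls
#' below the contact cutoff, with their native distances in Angstrom.
#'
#' @slot pairs integer matrix, columns `i`, `j`.
#' @slot nativeDist numeric vector of native distances (Angstrom).
#' @export
setClass("ContactSet",
  representation(pairs = "matrix", nativeDist = "numeric"))

setValidity("ContactSet", function(object) {
  p <- object@pairs
  if (nrow(p) < 1L) return("contact set must contain at least one pair")
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  if (any(p[, 2L] - p[, 1L] <= 3L))
    return("all pairs must be more than 3 residues apart along the chain")
  if (length(object@nativeDist) != nrow(p))
    return("one native distance per pair required")
  TRUE
})

#' Number of native contacts
#'
#' @param x a ContactSet or NativeReference.
#' @return integer: the number of native contact pairs (N_S).
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))

#' @rdname nContacts
#' @export
setMethod("nContacts", "ContactSet", function(x) nrow(x@pairs))

#' Contact pair table
#' @param x a ContactSet
#' @return data.frame with columns `i`, `j`, `nativeDist` (Angstrom).
#' @export
contactPairs <- function(x) {
  data.frame(i = x@pairs[, 1L], j = x@pairs[, 2L], nativeDist = x@nativeDist)
}

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet:", nrow(object@pairs), "native contacts, |i-j| in [",
      min(object@pairs[, 2] - object@pairs[, 1]), ",",
      max(object@pairs[, 2] - object@pairs[, 1]), "]\n")
})

#' Metric parameters
#'
#' Parameters of the internal-distance similarity (q) and the smoothed
#' fraction of native contacts (Q_o). `beta0` and `contactCutoff` are
#' accepted in the units they are conventionally printed in (nm^-1 and nm)
#' and converted internally to Angstrom units; `lam` is the dimensionless
#' native-distance multiplier of the Q_o logistic.
#'
#' @slot sigma0 Angstrom; base width of the q Gaussians (default 1).
#' @slot epsilon unitless exponent of the sequence-separation width growth
#'   (default 0.15).
#' @slot minSepQ minimum |i - j| of pairs entering q (default 3).
#' @slot beta0 nm^-1; Q_o logistic steepness (default 50).
#' @slot lam unitless native-distance multiplier (default 1.2).
#' @slot contactCutoff nm; native contact distance cutoff (default 1.2).
#' @export
setClass("MetricParams",
  representation(sigma0 = "numeric", epsilon = "numeric", minSepQ = "integer",
                 beta0 = "numeric", lam = "numeric", contactCutoff = "numeric"),
  prototype(sigma0 = 1.0, epsilon = 0.15, minSepQ = 3L, beta0 = 50,
            lam = 1.2, contactCutoff = 1.2))

setValidity("MetricParams", function(object) {
  if (object@sigma0 <= 0) return("sigma0 must be > 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (object@minSepQ < 1L) return("minSepQ must be >= 1")
  if (object@beta0 <= 0) return("beta0 must be > 0")
  if (object@lam <= 0) return("lam must be > 0")
  if (object@contactCutoff <= 0) return("contactCutoff must be > 0")
  TRUE
})

#' Construct metric parameters
#'
#' @param sigma0,epsilon,minSepQ,beta0,lam,contactCutoff see
#'   [MetricParams-class].
#' @return A [MetricParams-class].
#' @export
metricParams <- function(sigma0 = 1.0, epsilon = 0.15, minSepQ = 3L,
                         beta0 = 50, lam = 1.2, contactCutoff = 1.2) {
  new("MetricParams", sigma0 = sigma0, epsilon = epsilon,
      minSepQ = as.integer(minSepQ), beta0 = beta0, lam = lam,
      contactCutoff = contactCutoff)
}

# unit conversions: printed nm units -> internal Angstrom units
.betaA <- function(p) p@beta0 * 0.1      # nm^-1 -> A^-1
.cutoffA <- function(p) p@contactCutoff * 10  # nm -> A

setMethod("show", "MetricParams", function(object) {
  cat(sprintf(paste0("MetricParams: sigma0 = %g A, epsilon = %g, ",
                     "minSepQ = %d, beta0 = %g nm^-1, lam = %g, ",
                     "cutoff = %g nm\n"),
      object@sigma0, object@epsilon, object@minSepQ, object@beta0,
      object@lam, object@contactCutoff))
})

#' Native reference structure
#'
#' The folded reference of a repeat protein: native conformation, full native
#' pair-distance matrix, repeat boundaries and the native contact set.
#'
#' @slot native the native [Conformation-class].
#' @slot nativeDistances n x n native C-alpha distance matrix (Angstrom).
#' @slot repeats integer matrix with columns `start`, `end` (1-based,
#'   inclusive), ordered and non-overlapping.
#' @slot contacts the native [ContactSet-class].
#' @export
setClass("NativeReference",
  representation(native = "Conformation", nativeDistances = "matrix",
                 repeats = "matrix", contacts = "ContactSet"))

setValidity("NativeReference", function(object) {
  n <- nResidues(object@native)
  d <- object@nativeDistances
  if (!identical(dim(d), c(n, n)))
    return("nativeDistances must be n x n")
  if (max(abs(d - t(d))) > 1e-9) return("nativeDistances must be symmetric")
  r <- object@repeats
  if (ncol(r) != 2L) return("repeats must have columns start, end")
  if (any(r[, 1L] > r[, 2L])) return("each repeat must satisfy start <= end")
  if (nrow(r) > 1L && any(r[-1L, 1L] <= r[-nrow(r), 2L]))
    return("repeats must be ordered and non-overlapping")
  if (max(r) > n || min(r) < 1L) return("repeat ranges exceed the chain")
  cd <- .pairDistances(object@native@coords,
                       object@contacts@pairs[, 1L], object@contacts@pairs[, 2L])
  if (max(abs(cd - object@contacts@nativeDist)) > 1e-6)
    return("contact native distances inconsistent with native coordinates")
  TRUE
})

#' Construct a NativeReference
#'
#' Computes the native distance matrix and builds the native contact set from
#' the native conformation via [buildContactSet()].
#'
#' @param native the native [Conformation-class].
#' @param repeats repeat boundaries: integer matrix (or 2-column data.frame)
#'   with columns start, end, 1-based inclusive.
#' @param params [MetricParams-class]; sets the contact cutoff.
#' @return A [NativeReference-class].
#' @export
nativeReference <- function(native, repeats, params = metricParams()) {
  repeats <- as.matrix(repeats)
  storage.mode(repeats) <- "integer"
  colnames(repeats) <- c("start", "end")
  d <- as.matrix(dist(native@coords))
  dimnames(d) <- NULL
  new("NativeReference", native = native, nativeDistances = d,
      repeats = repeats, contacts = buildContactSet(native, params))
}

#' @export
setMethod("nResidues", "NativeReference", function(x) nResidues(x@native))

#' @rdname coords
#' @export
setMethod("coords", "NativeReference", function(x) x@native@coords)

#' @export
setMethod("nContacts", "NativeReference", function(x) nContacts(x@contacts))

#' Repeat boundaries of a NativeReference
#' @param x a NativeReference
#' @return integer matrix with columns `start`, `end`.
#' @export
repeatRanges <- function(x) x@repeats

#' Number of repeats
#' @param x a NativeReference
#' @export
nRepeats <- function(x) nrow(x@repeats)

# list of residue index vectors, one per repeat
.repeatMembers <- function(native) {
  lapply(seq_len(nrow(native@repeats)),
         function(r) seq(native@repeats[r, 1L], native@repeats[r, 2L]))
}

setMethod("show", "NativeReference", function(object) {
  cat("NativeReference:", nResidues(object), "residues,",
      nrow(object@repeats), "repeats,",
      nContacts(object@contacts), "native contacts\n")
})

# ---------------------------------------------------------------------------
# DissimilarityMatrix
# ---------------------------------------------------------------------------

#' Structural dissimilarity matrix
#'
#' Symmetric matrix of delta_kl = 1 - q_kl over an ensemble, the input of the
#' low-dimensional projection. delta is a dissimilarity, not a metric: the
#' triangle inequality is not guaranteed.
#'
#' @slot values symmetric numeric matrix with zero diagonal, entries in \eqn{[0, 1]}.
#' @export
setClass("DissimilarityMatrix", representation(values = "matrix"))

setValidity("DissimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (any(abs(diag(v)) > 0)) return("diagonal must be exactly zero")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
  if (min(v) < 0 || max(v) > 1) return("entries must lie in [0, 1]")
  TRUE
})

#' @param values symmetric dissimilarity matrix (zero diagonal, \eqn{[0, 1]}).
#' @rdname DissimilarityMatrix-class
#' @export
dissimilarity <- function(values) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("DissimilarityMatrix", values = values)
}

#' Dissimilarity values accessor
#' @param x a DissimilarityMatrix
#' @export
dissimilarityValues <- function(x) x@values

#' @export
setMethod("nFrames", "DissimilarityMatrix", function(x) nrow(x@values))

setMethod("show", "DissimilarityMatrix", function(object) {
  cat("DissimilarityMatrix:", nrow(object@values), "conformations, range [",
      sprintf("%.3f", min(object@values[upper.tri(object@values)])), ",",
      sprintf("%.3f", max(object@values)), "]\n")
})

# ---------------------------------------------------------------------------
# Projection / Augmented3D
# ---------------------------------------------------------------------------

#' Low-dimensional ensemble projection
#'
#' 2D coordinates per representative conformation obtained by stress
#' majorization of the dissimilarity matrix, plus the frame-to-representative
#' map and convergence diagnostics. Axis orientation and reflection are
#' arbitrary; downstream analyses must not depend on them.
#'
#' @slot coords numeric n_rep x 2 matrix.
#' @slot repOf integer vector mapping each input frame to its representative.
#' @slot representatives integer vector: the frame index of each
#'   representative in the original ensemble.
#' @slot stress final normalized squared stress.
#' @slot stressAbs mean absolute deviation |delta - d| (diagnostic).
#' @slot stressTrace per-iteration stress of the winning start.
#' @slot seed integer seed used.
#' @slot iterationsRun iterations of the winning start.
#' @export
setClass("Projection",
  representation(coords = "matrix", repOf = "integer",
                 representatives = "integer", stress = "numeric",
                 stressAbs = "numeric", stressTrace = "numeric",
                 seed = "integer", iterationsRun = "integer"))

setValidity("Projection", function(object) {
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (ncol(object@coords) != 2L) return("projection must be 2D")
  if (any(object@repOf < 1L) || any(object@repOf > nrow(object@coords)))
    return("repOf must map every frame to a representative")
  if (object@stress < 0) return("stress must be >= 0")
  TRUE
})

#' @rdname coords
#' @export
setMethod("coords", "Projection", function(x) x@coords)

#' Frame-to-representative map of a Projection
#' @param x a Projection
#' @export
representativeOf <- function(x) x@repOf

#' Final stress of a Projection
#' @param x a Projection
#' @export
projectionStress <- function(x) x@stress

setMethod("show", "Projection", function(object) {
  cat(sprintf("Projection: %d representatives (%d frames), stress %.3g, %d iterations\n",
      nrow(object@coords), length(object@repOf), object@stress,
      object@iterationsRun))
})

#' Projection augmented with a reaction-coordinate axis
#'
#' @slot coords3 numeric n_rep x 3 matrix; columns 1-2 are the source
#'   projection, column 3 the chosen reaction coordinate.
#' @export
setClass("Augmented3D", representation(coords3 = "matrix"))

#' @rdname coords
#' @export
setMethod("coords", "Augmented3D", function(x) x@coords3)

setMethod("show", "Augmented3D", function(object) {
  cat("Augmented3D:", nrow(object@coords3), "points, z in [",
      sprintf("%.3f", min(object@coords3[, 3])), ",",
      sprintf("%.3f", max(object@coords3[, 3])), "]\n")
})

# ---------------------------------------------------------------------------
# thermo types
# ---------------------------------------------------------------------------

#' Umbrella-sampling window
#'
#' Reaction-coordinate samples collected under a harmonic bias
#' (kSpring/2) (xi - center)^2, in kT units.
#'
#' @slot center bias center on the reaction coordinate.
#' @slot kSpring bias strength, kT per (coordinate unit)^2; >= 0.
#' @slot temperature simulation temperature, K.
#' @slot samples per-frame reaction-coordinate values.
#' @export
setClass("UmbrellaWindow",
  representation(center = "numeric", kSpring = "numeric",
                 temperature = "numeric", samples = "numeric"))

setValidity("UmbrellaWindow", function(object) {
  if (object@kSpring < 0) return("kSpring must be >= 0")
  if (length(object@samples) < 1L) return("window needs at least one sample")
  TRUE
})

#' Construct an UmbrellaWindow
#' @param center,kSpring,temperature,samples see [UmbrellaWindow-class].
#' @export
umbrellaWindow <- function(center, kSpring, samples, temperature = 300) {
  new("UmbrellaWindow", center = center, kSpring = kSpring,
      temperature = temperature, samples = as.numeric(samples))
}

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow: center %.3g, k %.3g kT, %d samples, T = %g K\n",
      object@center, object@kSpring, length(object@samples),
      object@temperature))
})

#' Binned free-energy profile
#'
#' Free energy in kT over reaction-coordinate bins, pinned so the minimum
#' over occupied bins is exactly zero. Unoccupied bins are flagged and carry
#' `NA`, never silently interpolated.
#'
#' @slot binCenters reaction-coordinate bin centers.
#' @slot freeEnergy kT per bin; `NA` where unoccupied.
#' @slot occupied logical mask of bins with data.
#' @export
setClass("FreeEnergyProfile",
  representation(binCenters = "numeric", freeEnergy = "numeric",
                 occupied = "logical"))

setValidity("FreeEnergyProfile", function(object) {
  if (length(object@freeEnergy) != length(object@binCenters) ||
      length(object@occupied) != length(object@binCenters))
    return("binCenters, freeEnergy and occupied must have equal length")
  occ <- object@freeEnergy[object@occupied]
  if (!all(is.finite(occ))) return("occupied bins must have finite F")
  if (length(occ) && abs(min(occ)) > 1e-9)
    return("minimum over occupied bins must be 0")
  TRUE
})

#' Free-energy accessor
#' @param x a FreeEnergyProfile
#' @return data.frame with columns `bin`, `F` (kT), `occupied`.
#' @export
freeEnergy <- function(x) {
  data.frame(bin = x@binCenters, F = x@freeEnergy, occupied = x@occupied)
}

setMethod("show", "FreeEnergyProfile", function(object) {
  cat(sprintf("FreeEnergyProfile: %d bins (%d occupied), F max %.3g kT\n",
      length(object@binCenters), sum(object@occupied),
      max(object@freeEnergy[object@occupied])))
})

#' @param x a FreeEnergyProfile
#' @param ... passed to [graphics::plot()]
#' @describeIn FreeEnergyProfile-class simple base-graphics profile plot
#' @export
setMethod("plot", signature(x = "FreeEnergyProfile", y = "missing"),
  function(x, ...) {
    graphics::plot(x@binCenters[x@occupied], x@freeEnergy[x@occupied],
                   type = "b", xlab = "reaction coordinate",
                   ylab = "F (kT)", ...)
  })

#' Melting curve
#'
#' Mean global reaction coordinate versus temperature with the estimated
#' folding temperature T_F (midpoint of the folded/unfolded transition).
#'
#' @slot temperatures K, strictly ascending.
#' @slot meanCoord mean Q_w per temperature, in \eqn{[0, 1]}.
#' @slot tF estimated folding temperature, K.
#' @slot method "logistic" or "interpolation".
#' @export
setClass("MeltingCurve",
  representation(temperatures = "numeric", meanCoord = "numeric",
                 tF = "numeric", method = "character"))

setValidity("MeltingCurve", function(object) {
  if (any(diff(object@temperatures) <= 0))
    return("temperatures must be strictly ascending")
  if (length(object@meanCoord) != length(object@temperatures))
    return("one mean coordinate per temperature required")
  if (min(object@meanCoord) < 0 || max(object@meanCoord) > 1)
    return("mean coordinate must lie in [0, 1]")
  TRUE
})

#' Folding temperature of a MeltingCurve
#' @param x a MeltingCurve
#' @export
foldingTemperature <- function(x) x@tF

setMethod("show", "MeltingCurve", function(object) {
  cat(sprintf("MeltingCurve: %d temperatures [%g, %g] K, T_F = %.1f K (%s)\n",
      length(object@temperatures), min(object@temperatures),
      max(object@temperatures), object@tF, object@method))
})

# ---------------------------------------------------------------------------
# LocalQProfile
# ---------------------------------------------------------------------------

#' Per-residue local folding profile
#'
#' One value in \eqn{[0, 1]} per residue; residues with no qualifying pairs or
#' contacts are flagged undefined (`NA`), never reported as 0.
#'
#' @slot perResidue numeric vector, `NA` where undefined.
#' @slot coordinateKind "q_local" or "Qo_local".
#' @export
setClass("LocalQProfile",
  representation(perResidue = "numeric", coordinateKind = "character"))

setValidity("LocalQProfile", function(object) {
  v <- object@perResidue[!is.na(object@perResidue)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("defined entries must lie in [0, 1]")
  if (!object@coordinateKind %in% c("q_local", "Qo_local"))
    return("coordinateKind must be q_local or Qo_local")
  TRUE
})

#' Per-residue values of a LocalQProfile
#' @param x a LocalQProfile
#' @export
profileValues <- function(x) x@perResidue

setMethod("show", "LocalQProfile", function(object) {
  cat(sprintf("LocalQProfile (%s): %d residues, %d undefined\n",
      object@coordinateKind, length(object@perResidue),
      sum(is.na(object@perResidue))))
})

# ---------------------------------------------------------------------------
# synthetic_data types
# ---------------------------------------------------------------------------

#' A folding-route specification
#'
#' Defines one repeat-by-repeat folding route for the synthetic ensemble
#' generator: the order in which repeats acquire native structure, the
#' positional noise on folded repeats, and the mixture weight when routes
#' are combined.
#'
#' @slot order integer permutation of repeat indices (folding order).
#' @slot nStages frames per folding stage when the caller does not fix a
#'   total frame count (`NA` = derive from `nFrames`).
#' @slot noiseFolded Angstrom Gaussian jitter applied to folded repeats.
#' @slot weight mixture fraction when combined.
#' @slot label route label stored in frame metadata.
#' @export
setClass("RouteSpec",
  representation(order = "integer", nStages = "integer",
                 noiseFolded = "numeric", weight = "numeric",
                 label = "character"))

setValidity("RouteSpec", function(object) {
  if (!identical(sort(object@order), seq_along(object@order)))
    return("order must be a permutation of 1..n_repeats")
  if (object@noiseFolded < 0) return("noiseFolded must be >= 0")
  if (object@weight < 0 || object@weight > 1)
    return("weight must lie in [0, 1]")
  TRUE
})

#' Construct a RouteSpec
#' @param order permutation of repeat indices giving the folding order.
#' @param noiseFolded Angstrom jitter on folded repeats (default 0.5).
#' @param weight mixture fraction (default 1).
#' @param nStages frames per stage when no total frame count is given.
#' @param label route label; defaults to the order spelled out.
#' @export
routeSpec <- function(order, noiseFolded = 0.5, weight = 1, nStages = NA,
                      label = paste0("R", paste(order, collapse = ">R"))) {
  new("RouteSpec", order = as.integer(order), nStages = as.integer(nStages),
      noiseFolded = noiseFolded, weight = weight, label = label)
}

setMethod("show", "RouteSpec", function(object) {
  cat(sprintf("RouteSpec %s: noise %.2g A, weight %.2g\n", object@label,
      object@noiseFolded, object@weight))
})

#' Parameters of the additive C-alpha Go model
#'
#' A funneled structure-based potential: harmonic bonds at the native bond
#' lengths, Gaussian attractive wells on native contacts, and soft harmonic
#' excluded volume on non-native pairs. Energies are in kT at the reference
#' temperature; kelvin temperatures map to reduced units via
#' kT(T) = T / tempRef.
#'
#' @slot bondK kT/A^2 (default 100).
#' @slot bondR0 A; bond length used by coil generation (default 3.8); the
#'   simulator restrains bonds at their native lengths.
#' @slot contactDepth kT per native contact (default 1.5).
#' @slot contactWidth A (default 1.0).
#' @slot excludedRadius A (default 4.0).
#' @slot excludedK kT/A^2 (default 20).
#' @slot tempRef K at which kT = 1 (default 300).
#' @slot dt integrator step, reduced time units (default 0.001); stable for
#'   dt < 0.1 * gamma / bondK.
#' @slot gamma friction (default 1).
#' @export
setClass("GoModelParams",
  representation(bondK = "numeric", bondR0 = "numeric",
                 contactDepth = "numeric", contactWidth = "numeric",
                 excludedRadius = "numeric", excludedK = "numeric",
                 tempRef = "numeric", dt = "numeric", gamma = "numeric"))

setValidity("GoModelParams", function(object) {
  vals <- c(object@bondK, object@bondR0, object@contactWidth,
            object@excludedRadius, object@excludedK, object@tempRef,
            object@dt, object@gamma)
  if (any(vals <= 0)) return("all Go-model parameters must be positive")
  if (object@contactDepth < 0) return("contactDepth must be >= 0")
  if (object@dt > 0.1 * object@gamma / object@bondK)
    return("dt exceeds the stability bound 0.1 * gamma / bondK")
  TRUE
})

#' Construct Go-model parameters
#' @param bondK,bondR0,contactDepth,contactWidth,excludedRadius,excludedK
#'   see [GoModelParams-class].
#' @param tempRef,dt,gamma see [GoModelParams-class].
#' @export
goModelParams <- function(bondK = 100, bondR0 = 3.8, contactDepth = 1.5,
                          contactWidth = 1.0, excludedRadius = 4.0,
                          excludedK = 20, tempRef = 300, dt = 0.001,
                          gamma = 1.0) {
  new("GoModelParams", bondK = bondK, bondR0 = bondR0,
      contactDepth = contactDepth, contactWidth = contactWidth,
      excludedRadius = excludedRadius, excludedK = excludedK,
      tempRef = tempRef, dt = dt, gamma = gamma)
}

setMethod("show", "GoModelParams", function(object) {
  cat(sprintf(paste0("GoModelParams: bondK %g, depth %g kT, width %g A, ",
      "excl %g A, dt %g, gamma %g, tempRef %g K\n"),
      object@bondK, object@contactDepth, object@contactWidth,
      object@excludedRadius, object@dt, object@gamma, object@tempRef))
})

#' A recorded simulation run
#'
#' @slot ensemble the recorded frames with per-frame `energy`, `qw`, `qo`
#'   in the scalar table.
#' @slot seed integer seed.
#' @slot bias numeric of length 0 (unbiased) or c(center, kSpring).
#' @slot temperature K.
#' @export
setClass("SimRun",
  representation(ensemble = "Ensemble", seed = "integer", bias = "numeric",
                 temperature = "numeric"))

setMethod("show", "SimRun", function(object) {
  cat(sprintf("SimRun: %d frames, T = %g K%s\n", nFrames(object@ensemble),
      object@temperature,
      if (length(object@bias)) sprintf(", bias center %.3g (k = %g)",
                                       object@bias[1], object@bias[2]) else ""))
})

#' Ensemble of a SimRun
#' @param x a SimRun
#' @export
runEnsemble <- function(x) x@ensemble

# ---------------------------------------------------------------------------
# route_analysis types
# ---------------------------------------------------------------------------

#' Residue-resolved folding heatmap
#'
#' Mean per-residue local Q_o conditioned on the global Q_o bin.
#'
#' @slot binEdges global-coordinate bin edges over \eqn{[0, 1]}.
#' @slot matrix residues x bins; `NA` for empty bins / undefined residues.
#' @slot counts frames per bin.
#' @export
setClass("FoldingHeatmap",
  representation(binEdges = "numeric", matrix = "matrix",
                 counts = "integer"))

setValidity("FoldingHeatmap", function(object) {
  if (ncol(object@matrix) != length(object@binEdges) - 1L)
    return("one matrix column per bin required")
  if (length(object@counts) != ncol(object@matrix))
    return("one count per bin required")
  v <- object@matrix[!is.na(object@matrix)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("heatmap entries must lie in [0, 1]")
  TRUE
})

#' Heatmap matrix accessor
#' @param x a FoldingHeatmap
#' @export
heatmapMatrix <- function(x) x@matrix

#' Frames per global-coordinate bin
#' @param x a FoldingHeatmap
#' @export
binCounts <- function(x) x@counts

setMethod("show", "FoldingHeatmap", function(object) {
  cat(sprintf("FoldingHeatmap: %d residues x %d bins, %d frames\n",
      nrow(object@matrix), ncol(object@matrix), sum(object@counts)))
})

#' A selected region of the projection
#'
#' @slot polygon 2D vertex matrix in projection space.
#' @slot representatives indices of representatives inside the polygon.
#' @slot frames member frame indices.
#' @export
setClass("RegionSelection",
  representation(polygon = "matrix", representatives = "integer",
                 frames = "integer"))

setValidity("RegionSelection", function(object) {
  if (length(object@frames) < 1L) return("region membership must be non-empty")
  TRUE
})

#' Member frames of a RegionSelection
#' @param x a RegionSelection
#' @export
memberFrames <- function(x) x@frames

setMethod("show", "RegionSelection", function(object) {
  cat(sprintf("RegionSelection: %d representatives, %d frames\n",
      length(object@representatives), length(object@frames)))
})

#' Commitment-probability estimate
#'
#' @slot nRuns replicas counted (aborted runs excluded).
#' @slot nFolded replicas reaching the success threshold within budget.
#' @slot fraction nFolded / nRuns.
#' @slot ci 95% Clopper-Pearson interval.
#' @slot threshold Q_o success cutoff.
#' @slot budget step budget per replica.
#' @slot nAborted simulator aborts, reported separately.
#' @export
setClass("CommitmentResult",
  representation(nRuns = "integer", nFolded = "integer", fraction = "numeric",
                 ci = "numeric", threshold = "numeric", budget = "numeric",
                 nAborted = "integer"))

setValidity("CommitmentResult", function(object) {
  if (object@fraction < 0 || object@fraction > 1)
    return("fraction must lie in [0, 1]")
  if (object@ci[1] > object@fraction + 1e-12 ||
      object@ci[2] < object@fraction - 1e-12)
    return("the confidence interval must contain the fraction")
  TRUE
})

#' Commitment fraction accessor
#' @param x a CommitmentResult
#' @export
commitmentFraction <- function(x) x@fraction

#' Commitment confidence interval accessor
#' @param x a CommitmentResult
#' @export
commitmentCI <- function(x) x@ci

setMethod("show", "CommitmentResult", function(object) {
  cat(sprintf("CommitmentResult: %d/%d folded (%.1f%%), 95%% CI [%.3f, %.3f]%s\n",
      object@nFolded, object@nRuns, 100 * object@fraction,
      object@ci[1], object@ci[2],
      if (object@nAborted) sprintf(", %d aborted", object@nAborted) else ""))
})
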