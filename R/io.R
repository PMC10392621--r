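#' Read a C-alpha structure from a PDB file
#'
#' Extracts C-alpha coordinates from one model of a PDB file, in file residue
#' order. Alternate locations are resolved to the highest-occupancy record;
#' chains with numbering gaps (chain breaks / missing residues) are rejected
#' rather than silently renumbered. Original PDB residue numbers and chain
#' identifiers are kept as metadata; all contracts use contiguous 1-based
#' indices after extraction.
#'
#' @param path PDB-format text file with at least one C-alpha per residue.
#' @param model model index for multi-model files (default 1).
#' @return A [Conformation-class] in Angstrom.
#' @export
readStructure <- function(path, model = 1L) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in '", path, "'")
  resid <- paste(atoms$chain, atoms$resno,
                 ifelse(is.na(atoms$insert), "", atoms$insert))
  resOrder <- unique(resid)
  ca <- atoms$elety == "CA"
  missing <- setdiff(resOrder, unique(resid[ca]))
  if (length(missing) > 0L)
    stop("residue(s) lacking a CA atom: ",
         paste(trimws(missing), collapse = ", "))
  # altloc: keep highest occupancy CA per residue (ties: first in file)
  caIdx <- which(ca)
  occ <- atoms$o[caIdx]
  occ[is.na(occ)] <- 1
  keep <- vapply(resOrder, function(r) {
    cand <- caIdx[resid[caIdx] == r]
    cand[which.max(occ[match(cand, caIdx)])]
  }, integer(1))
  # chain-break check: residue numbers must be contiguous within each chain
  chains <- atoms$chain[keep]
  resno <- atoms$resno[keep]
  for (ch in unique(chains)) {
    rn <- resno[chains == ch]
    if (length(rn) > 1L && any(diff(rn) != 1L))
      stop("chain ", ch, " has non-contiguous residue numbering (chain ",
           "break or missing residues); refusing to renumber silently")
  }
  nModels <- nrow(pdb$xyz)
  model <- as.integer(model)
  if (model < 1L || model > nModels)
    stop("model ", model, " requested but file has ", nModels, " model(s)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  conformation(xyz[keep, , drop = FALSE],
               meta = list(source = path, model = model,
                           pdbResno = resno, pdbChain = chains))
}

#' Read a trajectory as an Ensemble
#'
#' Supports multi-model PDB files (each MODEL becomes one frame, C-alpha
#' extraction as in [readStructure()]) and plain XYZ trajectories
#' (atom-count line, comment line, then `element x y z` rows per frame).
#'
#' @param path trajectory file.
#' @param fmt "pdb" (multi-model PDB) or "xyz".
#' @return An [Ensemble-class] in file frame order.
#' @export
readTrajectory <- function(path, fmt = c("pdb", "xyz")) {
  fmt <- match.arg(fmt)
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)
    nModels <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nModels), function(m) readStructure(path, m))
    return(ensemble(frames))
  }
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  frameIdx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frameIdx <- frameIdx + 1L
    nAtoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nAtoms) || nAtoms < 1L)
      stop("frame ", frameIdx, ": malformed atom-count line ", pos)
    if (pos + 1L + nAtoms > length(lines))
      stop("frame ", frameIdx, ": truncated (expected ", nAtoms, " atoms)")
    rows <- lines[(pos + 2L):(pos + 1L + nAtoms)]
    fields <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(fields) < 4L))
      stop("frame ", frameIdx, ": malformed coordinate line")
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("frame ", frameIdx, ": non-numeric coordinates")
    frames[[frameIdx]] <- conformation(xyz, meta = list(frame = frameIdx))
    pos <- pos + 2L + nAtoms
  }
  if (length(frames) == 0L) stop("no frames found in '", path, "'")
  ns <- vapply(frames, nResidues, integer(1))
  if (length(unique(ns)) != 1L) {
    bad <- which(ns != ns[1L])[1L]
    stop("inconsistent frame sizes: frame ", bad, " has ", ns[bad],
         " residues, frame 1 has ", ns[1L])
  }
  ensemble(frames)
}

#' Build the native contact set
#'
#' Native contacts are C-alpha pairs more than three residues apart along
#' the chain whose native distance is below the cutoff
#' (`contactCutoff`, given in nm and applied in Angstrom). The C-alpha
#' interpretation of the contact definition is a documented choice of this
#' coarse-grained representation.
#'
#' @param native the native [Conformation-class] (>= 5 residues).
#' @param params [MetricParams-class].
#' @return A [ContactSet-class] with native distances in Angstrom.
#' @export
buildContactSet <- function(native, params = metricParams()) {
  n <- nResidues(native)
  if (n < 5L) stop("native structure must have at least 5 residues")
  pairs <- .qualifyingPairs(n, 4L)  # |i - j| > 3
  d <- .pairDistances(native@coords, pairs[, 1L], pairs[, 2L])
  keep <- d < .cutoffA(params)
  if (!any(keep))
    stop("no native contacts below ", params@contactCutoff,
         " nm; increase contactCutoff")
  new("ContactSet", pairs = pairs[keep, , drop = FALSE],
      nativeDist = d[keep])
}

#' Write a rectangular table as TSV
#'
#' UTF-8, tab-separated, header row, deterministic column order (as given),
#' no quoting or row names.
#'
#' @param rows data.frame (may have zero rows).
#' @param path output file path.
#' @export
writeTable <- function(rows, path) {
  rows <- as.data.frame(rows)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write an Ensemble or Conformation as an XYZ trajectory
#'
#' @param x an [Ensemble-class] or [Conformation-class].
#' @param path output file.
#' @param element element symbol written per atom (default "CA").
#' @export
writeXYZ <- function(x, path, element = "CA") {
  fr <- if (is(x, "Ensemble")) x@frames else list(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(fr)) {
    xyz <- fr[[k]]@coords
    writeLines(c(as.character(nrow(xyz)), paste("frame", k)), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Write a minimal C-alpha PDB (fixture generation)
#'
#' Writes one MODEL per frame with one CA ATOM record per residue. Intended
#' for building small test fixtures and interoperating with PDB-consuming
#' tools; not a general-purpose PDB writer.
#'
#' @param x an [Ensemble-class] or [Conformation-class].
#' @param path output file.
#' @param chain chain identifier (default "A").
#' @export
writeCaPDB <- function(x, path, chain = "A") {
  fr <- if (is(x, "Ensemble")) x@frames else list(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  multi <- length(fr) > 1L
  for (k in seq_along(fr)) {
    xyz <- fr[[k]]@coords
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), chain, seq_len(nrow(xyz)),
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read metric parameters from a YAML or JSON config file
#'
#' The file holds a flat mapping mirroring the [MetricParams-class] field
#' names (`sigma0`, `epsilon`, `minSepQ`, `beta0`, `lam`, `contactCutoff`);
#' missing fields keep their defaults. `beta0` and `contactCutoff` are given
#' in nm units as conventionally printed.
#'
#' @param path YAML (or JSON) file.
#' @return A [MetricParams-class].
#' @export
metricParamsFromFile <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("sigma0", "epsilon", "minSepQ", "beta0", "lam", "contactCutoff")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  do.call(metricParams, cfg)
}
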