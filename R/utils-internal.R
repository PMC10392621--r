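# internal shared helpers

# distances between residue pairs (i, j) of one coordinate matrix
.pairDistances <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# qualifying pair set of Eq.-1-style similarity: i < j, j - i >= minSep
.qualifyingPairs <- function(n, minSep) {
  j <- sequence(n - seq_len(n - 1L), from = seq_len(n - 1L) + 1L)
  i <- rep.int(seq_len(n - 1L), n - seq_len(n - 1L))
  keep <- (j - i) >= minSep
  cbind(i = i[keep], j = j[keep])
}

# Gaussian variance per pair: sigma_ij = sigma0 * |i-j|^epsilon
.sigma2 <- function(pairs, params) {
  (params@sigma0 * (pairs[, 2L] - pairs[, 1L])^params@epsilon)^2
}

# per-frame pair-distance matrix (nFrames x nPairs)
.ensemblePairDistances <- function(ens, pairs) {
  t(vapply(ens@frames,
           function(f) .pairDistances(f@coords, pairs[, 1L], pairs[, 2L]),
           numeric(nrow(pairs))))
}

# Gaussian similarity terms of every frame against a reference distance
# vector: exp(-(d - d0)^2 / (2 sigma^2)), nFrames x nPairs
.pairTerms <- function(D, d0, s2) {
  exp(-sweep(sweep(D, 2L, d0)^2, 2L, 2 * s2, "/"))
}

# Q_o logistic terms per frame x contact: 1 / (1 + exp(beta (d - lam d0)))
.contactTerms <- function(ens, contacts, params) {
  D <- .ensemblePairDistances(ens, contacts@pairs)
  1 / (1 + exp(.betaA(params) *
               sweep(D, 2L, params@lam * contacts@nativeDist)))
}

.seedGuard <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
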