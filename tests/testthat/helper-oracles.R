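# Brute-force reference implementations and fixture builders shared by the
# test files. Oracles are deliberately naive double loops, independent of
# the package's vectorized/C++ code paths.

# plain Eq.-1-style similarity: double loop over all pairs |i-j| >= minSep
oracleQ <- function(A, B, sigma0 = 1, epsilon = 0.15, minSep = 3) {
  n <- nrow(A)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i < minSep) next
    ra <- sqrt(sum((A[i, ] - A[j, ])^2))
    rb <- sqrt(sum((B[i, ] - B[j, ])^2))
    s <- sigma0 * (j - i)^epsilon
    tot <- tot + exp(-(ra - rb)^2 / (2 * s^2))
    np <- np + 1
  }
  tot / np
}

# similarity restricted to pairs touching a focus residue set
oracleLocalQ <- function(A, B, focus, sigma0 = 1, epsilon = 0.15,
                         minSep = 3) {
  n <- nrow(A)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i < minSep) next
    if (!(i %in% focus || j %in% focus)) next
    ra <- sqrt(sum((A[i, ] - A[j, ])^2))
    rb <- sqrt(sum((B[i, ] - B[j, ])^2))
    s <- sigma0 * (j - i)^epsilon
    tot <- tot + exp(-(ra - rb)^2 / (2 * s^2))
    np <- np + 1
  }
  if (np == 0) return(NA_real_)
  tot / np
}

# smoothed fraction of native contacts over an explicit contact table
oracleQo <- function(X, pairs, r0, betaA = 5, lam = 1.2) {
  tot <- 0
  for (k in seq_len(nrow(pairs))) {
    r <- sqrt(sum((X[pairs[k, 1], ] - X[pairs[k, 2], ])^2))
    tot <- tot + 1 / (1 + exp(betaA * (r - lam * r0[k])))
  }
  tot / nrow(pairs)
}

# hard-cutoff contact occupancy over frames, all pairs |i-j| > 3
oracleContactMap <- function(frameList, cutA = 12) {
  n <- nrow(frameList[[1]])
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i <= 3) next
    hits <- 0
    for (f in frameList)
      if (sqrt(sum((f[i, ] - f[j, ])^2)) < cutA) hits <- hits + 1
    out <- rbind(out, c(i, j, hits / length(frameList)))
  }
  out
}

oracleRg <- function(X) {
  ctr <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
}

# random rigid motion: rotation (QR-orthogonalized Gaussian) + translation
randomRigid <- function(X) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% Q, 2, rnorm(3, sd = 10), "+")
}

randomChain <- function(n, scale = 4) {
  matrix(cumsum(rnorm(3 * n, sd = scale)), ncol = 3)
}

# small shared fixtures (built once per test run)
toyNative <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildToyNative(3L, 15L)
    cache
  }
})
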