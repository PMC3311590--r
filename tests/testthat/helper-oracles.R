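# Independent oracles used by the tests. These deliberately avoid the
# package's vectorised code paths: everything is scalar loops evaluated
# straight from the defining formulas.

AA20 <- aminoAcidAlphabet()

# Step-by-step evaluation of the full simulation chain
# (encode -> dot product -> association constant -> Langmuir fraction)
# for one peptide at a time.
oracleSignal <- function(seqs, h, A, conc,
                         R = 8.314472, Temp = 298.15,
                         beta0 = 0, beta1 = R * Temp) {
  vapply(seqs, function(sq) {
    res <- strsplit(sq, "")[[1L]]
    p <- numeric(length(res))
    for (j in seq_along(res)) p[j] <- h[[res[j]]]
    total <- 0
    for (k in seq_len(nrow(A))) {
      y <- 0
      for (j in seq_along(p)) y <- y + A[k, j] * p[j]
      K <- exp((beta0 + beta1 * y) / (R * Temp))
      total <- total + conc[k] * K
    }
    total / (1 + total)
  }, numeric(1L), USE.NAMES = FALSE)
}

# Ordinary-least-squares oracle via the normal equations (full-rank X).
oracleOls <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# assignments of the pooled observations to the two groups (no ties).
oracleRankSumP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  m <- length(b)
  stopifnot(!anyDuplicated(pooled))
  uStat <- function(x, y) sum(outer(x, y, ">"))
  uObs <- uStat(a, b)
  combs <- utils::combn(n + m, n)
  uAll <- apply(combs, 2L, function(idx)
    uStat(pooled[idx], pooled[-idx]))
  pLe <- mean(uAll <= uObs)
  pGe <- mean(uAll >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# Small library fixture built in code.
toyLibrary <- function(n = 30, l = 14, seed = 42) {
  generateLibrary(n, l, seed = seed)
}

# Simulate a normalized profile for given sizes, returning the pieces.
toySimulation <- function(nPep = 255, l = 14, nAb = 150, seedBase = 1,
                          sigma = 0) {
  lib <- generateLibrary(nPep, l, seed = seedBase)
  h <- sampleAssignedAAWS(seed = seedBase + 1)
  mix <- makeMixture(nAb, l, seed = seedBase + 2)
  prof <- simulateSignal(lib, mix, h)
  if (sigma > 0) prof <- applyNoise(prof, sigma, seed = seedBase + 3)
  list(lib = lib, X = compositionMatrix(lib), h = h, mix = mix,
       s = normalizeSignal(prof))
}
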