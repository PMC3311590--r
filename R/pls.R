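# Internal partial least squares engine (SIMPLS, univariate response).
#
# Returns the full coefficient path so that models with 1..ncomp components
# come out of a single pass; this is what makes nested component selection
# cheap enough for the ensemble experiments. When the centred predictor
# matrix has rank < ncomp the extraction stops at the rank and the path is
# padded with the last column: components beyond the rank contribute
# nothing. (The composition matrix of a fixed-length library always has
# this property - its rows sum to the peptide length, so the centred matrix
# has rank at most 19.)

.plsFit <- function(X, y, ncomp = 20L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  ncomp <- min(as.integer(ncomp), p, n - 1L)
  if (ncomp < 1L) stop("need at least 2 observations and 1 predictor")
  xMeans <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2L, xMeans)
  yc <- y - yMean
  if (sum(Xc^2) < 1e-300) stop("predictor matrix has rank 0 after centring")
  if (sd(y) < 1e-12) stop("response is constant")

  S <- crossprod(Xc, yc)                     # p x 1
  R <- matrix(0, p, ncomp)                   # X weights (direct)
  V <- matrix(0, p, ncomp)                   # orthonormal loading basis
  Q <- numeric(ncomp)                        # y loadings
  scale0 <- sqrt(sum((Xc %*% S)^2))
  covScale0 <- sqrt(sum(S^2))
  used <- 0L
  for (a in seq_len(ncomp)) {
    # stop once the remaining cross-covariance is numerically negligible:
    # later components only fit floating-point noise and degrade the fit
    if (sqrt(sum(S^2)) <= 1e-9 * max(covScale0, 1e-300)) break
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt <= 1e-10 * max(scale0, 1e-300)) break
    t <- t / nt
    r <- r / nt
    pl <- crossprod(Xc, t)
    Q[a] <- sum(yc * t)
    v <- pl
    if (a > 1L) {
      # iterated Gram-Schmidt for numerical stability near the rank
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, v)
      v <- v - Vp %*% crossprod(Vp, v)
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    R[, a] <- r
    S <- S - v %*% crossprod(v, S)
    used <- a
  }
  if (used == 0L) stop("no predictive component could be extracted")
  coefPath <- vapply(seq_len(used), function(k)
    drop(R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]), numeric(p))
  coefPath <- matrix(coefPath, nrow = p)
  if (ncol(coefPath) < ncomp)
    coefPath <- cbind(coefPath,
                      coefPath[, rep(ncol(coefPath), ncomp - ncol(coefPath)),
                               drop = FALSE])
  intercepts <- yMean - drop(crossprod(xMeans, coefPath))
  list(coefPath = coefPath, intercepts = intercepts, rank = used,
       xMeans = xMeans, yMean = yMean)
}

.plsPredict <- function(fit, X, k) {
  drop(as.matrix(X) %*% fit$coefPath[, k]) + fit$intercepts[k]
}

# Choose the number of components by 5-fold cross-validation on (X, y),
# minimising the pooled squared prediction error. Folds are assigned
# systematically (1, 2, ..., 5, 1, 2, ...) so the fit is a deterministic
# function of its inputs.
.plsSelectNcomp <- function(X, y, maxComp = 20L, innerFolds = 5L) {
  n <- nrow(X)
  folds <- rep_len(seq_len(innerFolds), n)
  maxComp <- min(maxComp, ncol(X), n - ceiling(n / innerFolds) - 1L)
  err <- matrix(NA_real_, n, maxComp)
  for (g in seq_len(innerFolds)) {
    te <- folds == g
    fit <- .plsFit(X[!te, , drop = FALSE], y[!te], maxComp)
    pred <- as.matrix(X[te, , drop = FALSE]) %*% fit$coefPath
    pred <- sweep(pred, 2L, fit$intercepts, "+")
    err[te, ] <- (pred - y[te])^2
  }
  which.min(colSums(err))
}
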