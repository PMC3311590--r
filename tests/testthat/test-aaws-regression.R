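test_that("noiseless composition signals recover the generating weights", {
  lib <- generateLibrary(255, 14, seed = 21)
  X <- compositionMatrix(lib)
  set.seed(22)
  w0 <- runif(20)
  s <- scale(drop(X %*% w0))[, 1]

  fit <- fitAAWS(s, X, nComponents = 20)
  expect_gt(cor(aawsWeights(fit), w0), 0.999)

  # default (cross-validated component count) recovers it too
  fitCv <- fitAAWS(s, X)
  expect_gt(cor(aawsWeights(fitCv), w0), 0.999)

  # residuals vanish for an exactly linear signal (the composition matrix
  # is rank-deficient, so convergence is governed by the component cutoff)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("PLS with all components equals the least-squares oracle", {
  # full-column-rank X: random counts without the fixed-row-sum constraint
  set.seed(31)
  X <- matrix(rpois(60 * 20, 2), 60, 20)
  colnames(X) <- aminoAcidAlphabet()
  y <- scale(rnorm(60))[, 1]

  fit <- fitAAWS(y, X, nComponents = 20)
  ols <- oracleOls(X, y)
  expect_lt(max(abs(aawsWeights(fit) - ols[-1])), 1e-8)
  expect_lt(abs(fit@intercept - ols[1]), 1e-8)
})

test_that("SIMPLS coefficient paths match mixOmics at every ncomp", {
  skip_if_not_installed("mixOmics")
  set.seed(41)
  X <- matrix(rnorm(50 * 8), 50, 8)
  colnames(X) <- paste0("x", 1:8)
  y <- rnorm(50)
  fit <- pepAAWS:::.plsFit(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  B <- predict(ref, newdata = X)$B.hat
  for (k in 1:3)
    expect_lt(max(abs(fit$coefPath[, k] - drop(B[, , k]))), 1e-10)
})

test_that("prediction is linear in composition counts", {
  w <- setNames(seq(-1, 0.9, by = 0.1), aminoAcidAlphabet())
  est <- new("AAWSEstimate", weights = w, intercept = 0.3,
             residuals = numeric(3), nComponents = 1L, fittedOn = "toy")

  X <- compositionMatrix(c(p1 = "AAC", p2 = "CDY", p3 = "YYY"))
  want <- drop(X %*% w) + 0.3
  expect_equal(predictSignal(X, est), want, tolerance = 1e-12)

  # one extra count of residue j moves the prediction by exactly w[j]
  X2 <- X
  X2["p1", "D"] <- X2["p1", "D"] + 1L
  expect_equal(predictSignal(X2, est)[["p1"]] -
                 predictSignal(X, est)[["p1"]],
               w[["D"]], tolerance = 1e-12)

  expect_error(predictSignal(X[, 1:5], est), "20 columns")
})

test_that("the Q2 statistic obeys its exact identities", {
  s <- scale(rnorm(40))[, 1]
  expect_identical(q2Statistic(s, s), 1)
  expect_identical(q2Statistic(s, rep(0, 40)), 0)
  expect_lt(q2Statistic(s, -s), 0)
})

test_that("cross-validated Q2 is near 1 for exactly linear signals", {
  lib <- generateLibrary(255, 14, seed = 51)
  X <- compositionMatrix(lib)
  set.seed(52)
  s <- scale(drop(X %*% runif(20)))[, 1]
  cv <- q2CrossValidation(s, X, seed = 53, nComponents = 19)
  expect_gt(q2(cv), 0.9999)
  expect_lte(q2(cv), 1)

  # fold bookkeeping
  expect_length(cv@foldAssignments, 255)
  expect_identical(sort(unique(cv@foldAssignments)), 1:10)
  expect_length(cv@perFoldPress, 10)
})

test_that("cross-validated Q2 hovers near zero for composition-free noise", {
  lib <- generateLibrary(255, 14, seed = 61)
  X <- compositionMatrix(lib)
  set.seed(62)
  s <- scale(rnorm(255))[, 1]
  cv <- q2CrossValidation(s, X, seed = 63)
  expect_lte(q2(cv), 1)
  expect_lt(abs(q2(cv)), 0.35)
})

test_that("Q2 is invariant to joint reordering of peptides and folds", {
  sim <- toySimulation(nPep = 120, nAb = 50, seedBase = 71)
  s <- profileValues(sim$s)
  set.seed(72)
  assign <- sample(rep_len(1:10, 120))
  cv1 <- q2CrossValidation(s, sim$X, nComponents = 10,
                           foldAssignments = assign)
  perm <- sample(120)
  cv2 <- q2CrossValidation(s[perm], sim$X[perm, ], nComponents = 10,
                           foldAssignments = assign[perm])
  # identical up to floating-point summation order
  expect_equal(q2(cv1), q2(cv2), tolerance = 1e-9)
})

test_that("cross-validation input contracts are enforced", {
  sim <- toySimulation(nPep = 40, nAb = 10, seedBase = 81)
  s <- profileValues(sim$s)
  expect_error(q2CrossValidation(s, sim$X, folds = 1, seed = 1), "folds")
  expect_error(q2CrossValidation(s, sim$X, folds = 30, seed = 1),
               "at least 2 peptides")
  expect_error(q2CrossValidation(s * 2, sim$X, seed = 1), "unit variance")
  expect_error(fitAAWS(s, sim$X[1:10, ]), "rows")
  expect_error(fitAAWS(s, sim$X, nComponents = 40), "1..20")
})

test_that("secondary-antibody correction recovers a known slope", {
  set.seed(91)
  logSec <- rnorm(255, 5, 1)
  logI <- 1 + 0.5 * logSec + rnorm(255, 0, 0.1)
  out <- secondaryCorrection(logI, logSec)
  expect_lt(abs(out$model@slope - 0.5), 0.05)
  v <- profileValues(out$profile)
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sd(v) - 1), 1e-9)

  # corrected profile equals the scaled residuals of the lm fit
  expect_equal(unname(v),
               unname(scale(resid(lm(logI ~ logSec)))[, 1]),
               tolerance = 1e-9)
})

test_that("secondary correction flags degenerate geometry", {
  set.seed(92)
  logSec <- rnorm(100)
  # exactly affine: residuals identically zero
  expect_error(secondaryCorrection(2 + 3 * logSec, logSec), "degenerate")
  # constant secondary channel: slope unidentifiable
  expect_error(secondaryCorrection(rnorm(100), rep(1, 100)), "constant")

  # uncorrelated secondary: correction is a no-op up to scaling
  logI <- rnorm(100)
  out <- secondaryCorrection(logI, logSec)
  expect_gt(cor(profileValues(out$profile), scale(logI)[, 1]), 0.99)
})
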