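test_that("pairwise AAWS correlations follow the covariance formula", {
  w <- runif(20)
  W <- rbind(w, 2 * w + 3, -w)
  r <- pairwiseAAWSCorrelation(W)
  expect_length(r, 3)
  expect_equal(r, c(1, -1, -1), tolerance = 1e-12)

  # against a direct formula evaluation on arbitrary vectors
  set.seed(7)
  W3 <- matrix(rnorm(60), 3, 20)
  manual <- c(
    sum((W3[1, ] - mean(W3[1, ])) * (W3[2, ] - mean(W3[2, ]))) /
      (19 * sd(W3[1, ]) * sd(W3[2, ])),
    sum((W3[1, ] - mean(W3[1, ])) * (W3[3, ] - mean(W3[3, ]))) /
      (19 * sd(W3[1, ]) * sd(W3[3, ])),
    sum((W3[2, ] - mean(W3[2, ])) * (W3[3, ] - mean(W3[3, ]))) /
      (19 * sd(W3[2, ]) * sd(W3[3, ])))
  expect_equal(pairwiseAAWSCorrelation(W3), manual, tolerance = 1e-12)

  # m estimates give m(m-1)/2 values, all in [-1, 1]
  W5 <- matrix(rnorm(100), 5, 20)
  r5 <- pairwiseAAWSCorrelation(W5)
  expect_length(r5, 10)
  expect_true(all(r5 >= -1 & r5 <= 1))

  W5[2, ] <- 4
  expect_error(pairwiseAAWSCorrelation(W5), "constant")
  expect_error(pairwiseAAWSCorrelation(W5[1, , drop = FALSE]),
               "at least 2")
})

test_that("h-recovery is an affine-invariant correlation", {
  h <- sampleAssignedAAWS(seed = 2)
  expect_equal(hRecovery(3 * aawsWeights(h) + 0.2, h), 1, tolerance = 1e-12)
  expect_equal(hRecovery(-aawsWeights(h), h), -1, tolerance = 1e-12)
  expect_error(hRecovery(rep(1, 20), h), "zero-variance")
})

test_that("diversity sweep has the declared shape and reproducibility", {
  lib <- generateLibrary(80, 14, seed = 5)
  h <- sampleAssignedAAWS(seed = 6)
  sw <- diversitySweep(lib, h, nAbGrid = c(1, 256), reps = 4, seed = 7,
                       folds = 5)
  expect_s4_class(sw, "SweepResult")
  expect_identical(sw@nAbGrid, c(1L, 256L))
  expect_true(all(lengths(sw@q2Samples) == 4))
  expect_true(all(lengths(sw@hRecoverySamples) == 4))
  expect_true(all(lengths(sw@pairwiseRSamples) == 6))  # 4*3/2 pairs

  # identical master seed reproduces every sample
  sw2 <- diversitySweep(lib, h, nAbGrid = c(1, 256), reps = 4, seed = 7,
                        folds = 5)
  expect_identical(sw@q2Samples, sw2@q2Samples)
  expect_identical(sw@pairwiseRSamples, sw2@pairwiseRSamples)

  # long-format export covers every metric
  tab <- as.data.frame(sw)
  expect_identical(sort(unique(tab$metric)),
                   c("h_recovery", "pairwise_r", "q2"))
  expect_identical(nrow(tab), 2L * (4L + 4L + 6L))

  # singleton replicates give empty pairwise samples
  sw1 <- diversitySweep(lib, h, nAbGrid = 16, reps = 1, seed = 8,
                        folds = 5)
  expect_length(sw1@pairwiseRSamples[[1]], 0)

  # regenerating the library per replicate still runs and differs
  sw3 <- diversitySweep(lib, h, nAbGrid = 16, reps = 2, seed = 9,
                        folds = 5, regenerateLibrary = TRUE)
  expect_length(sw3@q2Samples[[1]], 2)
})

test_that("diversity raises both Q2 and h-recovery", {
  lib <- generateLibrary(255, 14, seed = 15)
  h <- sampleAssignedAAWS(seed = 16)
  sw <- diversitySweep(lib, h, nAbGrid = c(1, 4096), reps = 5, seed = 17)
  expect_gt(median(sw@q2Samples[[2]]), median(sw@q2Samples[[1]]))
  expect_gt(median(sw@hRecoverySamples[[2]]),
            median(sw@hRecoverySamples[[1]]))
  expect_gt(median(sw@pairwiseRSamples[[2]]),
            median(sw@pairwiseRSamples[[1]]))
})

test_that("dominance cases reduce correctly and dominance hurts", {
  lib <- generateLibrary(100, 14, seed = 25)
  h <- sampleAssignedAAWS(seed = 26)

  # with sigma = 0 cases I and II coincide exactly (matched seeds)
  dom0 <- dominanceExperiment(lib, h, reps = 2, nAb = 300, sigma = 0,
                              seed = 27, folds = 5)
  expect_identical(dom0$I@q2Samples, dom0$II@q2Samples)

  # heavy dominance wrecks composition-only prediction
  dom <- dominanceExperiment(lib, h, reps = 3, nAb = 2000, sigma = 0.01,
                             seed = 28, folds = 5)
  expect_identical(names(dom), c("I", "II", "III", "IV"))
  expect_identical(dom$IV@dominanceFactor, 1000)
  expect_gt(median(dom$I@q2Samples), median(dom$IV@q2Samples))
  expect_gt(median(dom$I@pairwiseRSamples),
            median(dom$IV@pairwiseRSamples))

  tab <- as.data.frame(dom$III)
  expect_identical(unique(tab$case), "III")
})

test_that("PCA of AAWS separates shifted groups and orders variance", {
  set.seed(35)
  base <- matrix(rnorm(10 * 20, sd = 0.2), 10, 20)
  shift <- rep(c(0, 3), each = 5)
  W <- base + shift
  pc <- pcaAAWS(W, k = 2)
  expect_s4_class(pc, "PcaResult")

  # PC1 splits the groups; its variance fraction dominates
  s1 <- pc@scores[, 1]
  expect_true(max(s1[1:5]) < min(s1[6:10]) ||
              max(s1[6:10]) < min(s1[1:5]))
  expect_gt(pc@varianceExplained[1], 0.8)
  expect_true(all(diff(pc@varianceExplained) <= 1e-12))
  expect_lte(sum(pc@varianceExplained), 1 + 1e-9)

  # rank-1 input concentrates all variance on PC1
  u <- rnorm(6)
  W1 <- outer(u, rnorm(20))
  pc1 <- pcaAAWS(W1, k = 2)
  expect_equal(pc1@varianceExplained, c(1, 0), tolerance = 1e-9)

  # full-rank scores preserve pairwise distances of the centred data
  W6 <- matrix(rnorm(120), 6, 20)
  pc6 <- pcaAAWS(W6, k = 5)
  expect_equal(as.matrix(dist(pc6@scores)),
               as.matrix(dist(scale(W6, scale = FALSE))),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(pcaAAWS(W6, k = 6), "k must")
})

test_that("scale correlations align amino acids and honour the method", {
  w <- sampleAssignedAAWS(seed = 45)
  wv <- aawsWeights(w)

  tab <- data.frame(aa = aminoAcidAlphabet(),
                    self = unname(wv),
                    noise = rnorm(20),
                    flat = 1)
  r <- suppressWarnings(correlateWithScale(w, tab))
  expect_equal(unname(r["self"]), 1, tolerance = 1e-12)
  expect_true(is.na(r["flat"]))
  expect_warning(correlateWithScale(w, tab), "flat")

  # row order must not matter
  perm <- sample(20)
  r2 <- correlateWithScale(w, tab[perm, c("aa", "self", "noise")])
  expect_equal(unname(r2["noise"]), unname(r["noise"]), tolerance = 1e-12)

  # spearman equals rank-then-pearson
  set.seed(46)
  scaleCol <- rnorm(20)
  tabS <- data.frame(aa = aminoAcidAlphabet(), s = scaleCol)
  rs <- correlateWithScale(w, tabS, method = "spearman")
  expect_equal(unname(rs["s"]), cor(rank(wv), rank(scaleCol)),
               tolerance = 1e-12)

  expect_error(correlateWithScale(w, tab[-3, ]), tab$aa[3])
})

test_that("group comparison matches the exact rank-sum enumeration", {
  # identical groups: no evidence of a difference
  expect_gt(compareGroups(1:10, 1:10), 0.9)

  # disjoint support: overwhelming evidence
  expect_lt(compareGroups(rnorm(15), rnorm(15) + 100), 0.001)

  # exact p-value on a small fixed instance vs exhaustive enumeration
  a <- c(1.2, 3.4, 0.5, 2.2)
  b <- c(4.1, 5.0, 2.9, 6.3)
  expect_equal(compareGroups(a, b), oracleRankSumP(a, b),
               tolerance = 1e-12)

  expect_error(compareGroups(numeric(0), 1:5), "at least 3")
})
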