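#' Pairwise correlation of a set of AAWS estimates
#'
#' Pearson correlation of every unordered pair of 20-vectors; `m` estimates
#' give `m(m-1)/2` values (upper triangle, no diagonal). High pairwise
#' correlation means the estimates agree on the per-amino-acid contribution
#' regardless of which antibody mixture realisation produced them - the
#' ensemble signature of an unbiased mixture.
#'
#' @param W A list of [AAWSEstimate][AAWS-classes] objects (or numeric
#'   20-vectors), or an `m x 20` numeric matrix with one estimate per row.
#' @return Numeric vector of `m(m-1)/2` correlations in `[-1, 1]`, ordered
#'   as pairs (1,2), (1,3), (2,3), (1,4), ...
#' @examples
#' W <- rbind(1:20, 2 * (1:20) + 3, 20:1) / 20
#' pairwiseAAWSCorrelation(W)
#' @export
pairwiseAAWSCorrelation <- function(W) {
  M <- .aawsMatrix(W)
  if (nrow(M) < 2L) stop("need at least 2 AAWS estimates")
  sds <- apply(M, 1L, sd)
  if (any(sds < 1e-12))
    stop("constant AAWS vector(s) at row(s) ",
         paste(which(sds < 1e-12), collapse = ", "),
         ": correlation undefined")
  C <- cor(t(M))
  C[upper.tri(C)]
}

#' Recovery correlation between estimated and assigned weights
#'
#' Pearson correlation of a fitted AAWS 20-vector with the generative
#' assigned weights `h`. Values near 1 mean the composition-only regression
#' identified the simulator's per-residue binding strengths.
#'
#' @param w An [AAWSEstimate][AAWS-classes] or numeric 20-vector.
#' @param h An [AssignedAAWS][AAWS-classes] or numeric 20-vector.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' h <- sampleAssignedAAWS(seed = 1)
#' hRecovery(2 * aawsWeights(h) + 1, h)  # affine transform: r = 1
#' @export
hRecovery <- function(w, h) {
  wv <- if (is(w, "AAWSEstimate")) aawsWeights(w) else .canonical20(w)
  hv <- if (is(h, "AssignedAAWS")) aawsWeights(h) else .canonical20(h)
  if (sd(wv) < 1e-12 || sd(hv) < 1e-12)
    stop("zero-variance weight vector: correlation undefined")
  unname(cor(wv, hv))
}

#' Antibody-diversity sweep
#'
#' The central ensemble experiment: for each mixture size in `nAbGrid` and
#' each replicate, a fresh random antibody mixture is drawn, its binding to
#' the (fixed) library is simulated, the profile is normalized, the
#' composition-only model is fitted, and cross-validated Q2 plus recovery of
#' the assigned weights are recorded. Pairwise correlations among the
#' replicate AAWS estimates are computed per grid point. The peptide library
#' and the assigned weights are held fixed across all runs by default;
#' `regenerateLibrary = TRUE` draws a new library per replicate instead
#' (this leaves the distributions essentially unchanged).
#'
#' @param lib A [PeptideLibrary].
#' @param h An [AssignedAAWS][AAWS-classes].
#' @param nAbGrid Integer vector of mixture sizes; default powers of 4 from
#'   1 to 16384.
#' @param reps Replicate mixtures per grid point (default 100).
#' @param sigma Multiplicative noise standard deviation (default 0, no
#'   noise).
#' @param theta A [ThermoParams-class] object.
#' @param seed Integer master seed; per-stage sub-seeds (mixtures, noise,
#'   folds, libraries) are derived from it so that each randomness source
#'   has its own stream.
#' @param folds,nComponents Passed to [q2CrossValidation()].
#' @param regenerateLibrary Draw a fresh library for every replicate.
#' @return A [SweepResult-class].
#' @examples
#' lib <- generateLibrary(60, 14, seed = 1)
#' h <- sampleAssignedAAWS(seed = 2)
#' sw <- diversitySweep(lib, h, nAbGrid = c(1, 64), reps = 3, seed = 3)
#' as.data.frame(sw)[1:4, ]
#' @export
diversitySweep <- function(lib, h, nAbGrid = 4L^(0:7), reps = 100L,
                           sigma = 0, theta = thermoParams(), seed = NULL,
                           folds = 10L, nComponents = NULL,
                           regenerateLibrary = FALSE) {
  stopifnot(is(lib, "PeptideLibrary"))
  if (length(nAbGrid) < 1L) stop("nAbGrid must be non-empty")
  if (!.isCount(reps)) stop("reps must be a positive integer")
  nAbGrid <- as.integer(nAbGrid)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  nG <- length(nAbGrid)
  reps <- as.integer(reps)
  seedTab <- matrix(.deriveSeeds(seed, 4L * nG * reps), nG * reps, 4L)

  l <- peptideLength(lib)
  q2s <- hrs <- prs <- vector("list", nG)
  for (gi in seq_len(nG)) {
    Wmat <- matrix(NA_real_, reps, 20L)
    q2v <- hrv <- numeric(reps)
    for (r in seq_len(reps)) {
      sd4 <- seedTab[(gi - 1L) * reps + r, ]
      libR <- lib
      if (isTRUE(regenerateLibrary))
        libR <- generateLibrary(length(lib), l, seed = sd4[4L])
      X <- compositionMatrix(libR)
      mix <- makeMixture(nAbGrid[gi], l, seed = sd4[1L])
      prof <- simulateSignal(libR, mix, h, theta)
      if (sigma > 0) prof <- applyNoise(prof, sigma, seed = sd4[2L])
      s <- normalizeSignal(prof)
      fit <- fitAAWS(s, X, nComponents = nComponents,
                     fittedOn = sprintf("nAb=%d rep=%d", nAbGrid[gi], r))
      Wmat[r, ] <- aawsWeights(fit)
      hrv[r] <- hRecovery(fit, h)
      q2v[r] <- q2(q2CrossValidation(s, X, folds = folds, seed = sd4[3L],
                                     nComponents = nComponents))
    }
    q2s[[gi]] <- q2v
    hrs[[gi]] <- hrv
    prs[[gi]] <- if (reps > 1L) pairwiseAAWSCorrelation(Wmat) else numeric(0)
  }
  new("SweepResult", nAbGrid = nAbGrid, q2Samples = q2s,
      pairwiseRSamples = prs, hRecoverySamples = hrs)
}

#' Noise and antibody-dominance experiment
#'
#' Runs the four canonical perturbation cases on mixtures of `nAb`
#' antibodies: I (no noise, no dominance), II (multiplicative noise), III
#' (noise + 10-fold dominant antibody), IV (noise + 1000-fold dominant
#' antibody). One dominant antibody is drawn once at the start and kept
#' constant across all cases and replicates; each replicate draws a fresh
#' background mixture of `nAb - 1` antibodies to which the dominant antibody
#' is added. Background-mixture, noise and fold seeds are matched across
#' cases within a replicate, so case contrasts are paired.
#'
#' @inheritParams diversitySweep
#' @param nAb Mixture size (default 16000).
#' @param sigma Noise level for cases II-IV (default 0.01).
#' @return Named list of four [DominanceResult-class] objects
#'   (`"I"`..`"IV"`).
#' @examples
#' lib <- generateLibrary(60, 14, seed = 1)
#' h <- sampleAssignedAAWS(seed = 2)
#' dom <- dominanceExperiment(lib, h, reps = 2, nAb = 500, seed = 3)
#' vapply(dom, function(d) median(d@q2Samples), 0)
#' @export
dominanceExperiment <- function(lib, h, reps = 100L, nAb = 16000L,
                                sigma = 0.01, theta = thermoParams(),
                                seed = NULL, folds = 10L,
                                nComponents = NULL) {
  stopifnot(is(lib, "PeptideLibrary"))
  if (!.isCount(reps)) stop("reps must be a positive integer")
  if (!.isCount(nAb) || nAb < 2L) stop("nAb must be an integer >= 2")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  reps <- as.integer(reps)
  allSeeds <- .deriveSeeds(seed, 1L + 3L * reps)
  l <- peptideLength(lib)
  X <- compositionMatrix(lib)
  dominant <- sampleAntibody(l, seed = allSeeds[1L])
  repSeeds <- matrix(allSeeds[-1L], reps, 3L)

  cases <- list(I   = c(sigma = 0,     factor = 1),
                II  = c(sigma = sigma, factor = 1),
                III = c(sigma = sigma, factor = 10),
                IV  = c(sigma = sigma, factor = 1000))
  out <- lapply(names(cases), function(cs) {
    pars <- cases[[cs]]
    Wmat <- matrix(NA_real_, reps, 20L)
    q2v <- numeric(reps)
    for (r in seq_len(reps)) {
      mix <- makeMixture(nAb, l, seed = repSeeds[r, 1L],
                         dominanceFactor = pars[["factor"]],
                         dominant = dominant)
      prof <- simulateSignal(lib, mix, h, theta)
      if (pars[["sigma"]] > 0)
        prof <- applyNoise(prof, pars[["sigma"]], seed = repSeeds[r, 2L])
      s <- normalizeSignal(prof)
      fit <- fitAAWS(s, X, nComponents = nComponents,
                     fittedOn = sprintf("case=%s rep=%d", cs, r))
      Wmat[r, ] <- aawsWeights(fit)
      q2v[r] <- q2(q2CrossValidation(s, X, folds = folds,
                                     seed = repSeeds[r, 3L],
                                     nComponents = nComponents))
    }
    new("DominanceResult", case = cs, sigma = unname(pars[["sigma"]]),
        dominanceFactor = unname(pars[["factor"]]), q2Samples = q2v,
        pairwiseRSamples = if (reps > 1L) pairwiseAAWSCorrelation(Wmat)
                           else numeric(0))
  })
  names(out) <- names(cases)
  out
}

#' Principal component analysis of a set of AAWS
#'
#' Column-centred PCA (no variance scaling by default) of an `n x 20` AAWS
#' matrix, projecting the samples onto the first `k` principal components.
#' Used to ask whether groups of samples differ systematically in their
#' amino-acid weights.
#'
#' @param W `n x 20` numeric matrix (rows = samples) or list of
#'   [AAWSEstimate][AAWS-classes] objects.
#' @param k Number of components to keep (default 2).
#' @param scale Scale columns to unit variance before the decomposition.
#' @return A [PcaResult-class].
#' @examples
#' W <- rbind(matrix(rnorm(100, 0), 5), matrix(rnorm(100, 2), 5))
#' pcaAAWS(W, k = 2)
#' @export
pcaAAWS <- function(W, k = 2L, scale = FALSE) {
  M <- .aawsMatrix(W)
  if (nrow(M) < 2L) stop("need at least 2 samples")
  kmax <- min(nrow(M) - 1L, ncol(M))
  if (!.isCount(k) || k > kmax)
    stop("k must be an integer in 1..", kmax)
  k <- as.integer(k)
  pc <- prcomp(M, center = TRUE, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaResult",
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      varianceExplained = ve[seq_len(k)])
}

#' Correlate average AAWS with amino-acid property scales
#'
#' Aligns a user-supplied table of per-amino-acid property or propensity
#' scales (z-scales, hydrophilicity, antigenicity, accessibility, ...) with
#' an average AAWS vector and reports one correlation per scale column.
#' Scale values are user inputs, not bundled constants.
#'
#' @param wAvg An [AAWSEstimate][AAWS-classes] or numeric 20-vector (named
#'   by amino acid, or in canonical order).
#' @param scaleTable A data frame whose first column (or row names) holds
#'   the 20 one-letter codes and whose remaining numeric columns are scales,
#'   or a named numeric matrix with 20 rows. See [readScaleTable()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Named numeric vector, one correlation per scale column; a
#'   zero-variance scale column yields `NA` with a warning.
#' @examples
#' w <- sampleAssignedAAWS(seed = 1)
#' tab <- data.frame(aa = aminoAcidAlphabet(),
#'                   self = unname(aawsWeights(w)))
#' correlateWithScale(w, tab)  # r = 1 against itself
#' @export
correlateWithScale <- function(wAvg, scaleTable,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wv <- if (is(wAvg, "AAWSEstimate") || is(wAvg, "AssignedAAWS"))
    aawsWeights(wAvg) else .canonical20(wAvg)

  if (is.data.frame(scaleTable) && !is.numeric(scaleTable[[1L]])) {
    aa <- toupper(as.character(scaleTable[[1L]]))
    M <- as.matrix(scaleTable[, -1L, drop = FALSE])
  } else {
    M <- as.matrix(scaleTable)
    aa <- rownames(M)
    if (is.null(aa)) stop("scale table must name its amino-acid rows")
  }
  missing <- setdiff(.AA20, aa)
  if (length(missing))
    stop("scale table is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  M <- M[match(.AA20, aa), , drop = FALSE]
  if (!is.numeric(M)) stop("scale columns must be numeric")

  vapply(colnames(M), function(cn) {
    col <- M[, cn]
    if (sd(col) < 1e-12) {
      warning("scale '", cn, "' is constant: correlation undefined")
      return(NA_real_)
    }
    cor(wv, col, method = method)
  }, numeric(1L))
}

#' Compare two groups of values by rank-sum test
#'
#' Two-sided, non-paired Wilcoxon rank sum test, the package's standard
#' group comparison for Q2 or pairwise-correlation samples. P-values below
#' 0.05 are conventionally regarded as significant.
#'
#' @param valuesA,valuesB Numeric vectors with at least 3 values each.
#' @return The two-sided p-value.
#' @examples
#' compareGroups(rnorm(15), rnorm(15, 3))
#' @export
compareGroups <- function(valuesA, valuesB) {
  if (length(valuesA) < 3L || length(valuesB) < 3L)
    stop("each group needs at least 3 values")
  suppressWarnings(wilcox.test(valuesA, valuesB,
                               alternative = "two.sided")$p.value)
}

# Coerce a list of estimates / vectors, or a matrix, to an m x 20 matrix.
.aawsMatrix <- function(W) {
  if (is.list(W) && !is.data.frame(W)) {
    rows <- lapply(W, function(w)
      if (is(w, "AAWSEstimate") || is(w, "AssignedAAWS")) aawsWeights(w)
      else .canonical20(w))
    M <- do.call(rbind, rows)
  } else {
    M <- as.matrix(W)
  }
  if (ncol(M) != 20L) stop("AAWS matrix must have 20 columns")
  colnames(M) <- .AA20
  M
}
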