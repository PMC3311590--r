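#' Fit amino-acid-associated weights by partial least squares
#'
#' Fits the composition-only linear model `s = X w + e` relating a
#' normalized binding profile to the amino-acid composition matrix of the
#' peptide library, by partial least squares regression (SIMPLS). The
#' 20-vector `w` of amino-acid-associated weights gives the contribution of
#' each amino acid to the normalized signal intensity; the residuals capture
#' everything composition cannot explain (in particular all positional
#' effects).
#'
#' By default the number of PLS components is chosen per fit by an internal
#' deterministic 5-fold cross-validation over 1..20 components, minimising
#' squared prediction error; pass an integer `nComponents` for a fixed
#' component count. With all components retained on a full-column-rank
#' predictor matrix, PLS coincides with ordinary least squares.
#'
#' @param s A normalized [BindingProfile], or a numeric vector with mean 0
#'   and unit standard deviation.
#' @param X Composition matrix ([compositionMatrix()]): one row per peptide,
#'   20 columns in canonical alphabet order.
#' @param nComponents Integer in 1..20, or `NULL` (default) for internal
#'   cross-validated selection.
#' @param fittedOn Optional label stored with the estimate.
#'
#' @return An [AAWSEstimate][AAWS-classes].
#' @examples
#' lib <- generateLibrary(100, 14, seed = 1)
#' X <- compositionMatrix(lib)
#' h <- sampleAssignedAAWS(seed = 2)
#' s <- normalizeSignal(simulateSignal(lib, makeMixture(200, 14, seed = 3), h))
#' fit <- fitAAWS(s, X)
#' cor(aawsWeights(fit), aawsWeights(h))
#' @export
fitAAWS <- function(s, X, nComponents = NULL, fittedOn = "profile") {
  y <- .normalizedVector(s)
  X <- .checkCompositionInput(X, length(y))
  if (is.null(nComponents)) {
    k <- .plsSelectNcomp(X, y)
  } else {
    if (!.isCount(nComponents) || nComponents > 20)
      stop("nComponents must be an integer in 1..20")
    k <- as.integer(nComponents)
  }
  fit <- .plsFit(X, y, max(k, 1L))
  k <- min(k, ncol(fit$coefPath))
  w <- setNames(fit$coefPath[, k], colnames(X))
  pred <- .plsPredict(fit, X, k)
  AAWSEstimate(weights = w,
               intercept = fit$intercepts[k],
               residuals = setNames(y - pred, rownames(X)),
               nComponents = as.integer(k),
               fittedOn = as.character(fittedOn))
}

#' Predict a binding profile from amino-acid composition
#'
#' `s_hat = X w + intercept`: the model is linear in the composition counts,
#' so adding one occurrence of amino acid `j` to a peptide changes its
#' predicted signal by exactly `w[j]`.
#'
#' @param X Composition matrix (rows may be any set of peptides with the
#'   canonical 20 columns).
#' @param fit An [AAWSEstimate][AAWS-classes].
#' @return Named numeric vector of predicted normalized intensities.
#' @examples
#' lib <- generateLibrary(50, 14, seed = 1)
#' X <- compositionMatrix(lib)
#' h <- sampleAssignedAAWS(seed = 2)
#' s <- normalizeSignal(simulateSignal(lib, makeMixture(100, 14, seed = 3), h))
#' fit <- fitAAWS(s, X)
#' head(predictSignal(X, fit))
#' @export
predictSignal <- function(X, fit) {
  stopifnot(is(fit, "AAWSEstimate"))
  X <- .checkCompositionInput(X, nrow(as.matrix(X)))
  setNames(drop(as.matrix(X) %*% fit@weights) + fit@intercept, rownames(X))
}

#' Cross-validated predictive performance Q2
#'
#' Randomly partitions the peptides into `folds` groups, fits the
#' composition-only PLS model on each training remainder and predicts the
#' left-out fold, then pools all left-out predictions into
#' \deqn{Q^2 = 1 - \frac{\sum (\hat{s}_{left-out} - s_{left-out})^2}
#'                     {\sum s_{left-out}^2}.}
#' `Q2 = 1` means perfect prediction; values near or below zero mean the
#' model predicts no better than the zero (mean) predictor. The denominator
#' is the raw sum of squares of the left-out values; since the profile is
#' globally centred this approximates the total variance.
#'
#' @inheritParams fitAAWS
#' @param folds Number of folds (default 10, i.e. each left-out test set is
#'   a randomly chosen 10 percent of the peptides).
#' @param seed Integer seed for the fold assignment; `NULL` uses the current
#'   RNG stream.
#' @param nComponents Integer for a fixed component count, or `NULL` to
#'   reselect per training fold by internal cross-validation.
#' @param foldAssignments Optional integer vector assigning each peptide to
#'   a fold, overriding the random partition.
#' @return A [CvResult-class]; extract the performance with [q2()].
#' @examples
#' lib <- generateLibrary(120, 14, seed = 1)
#' X <- compositionMatrix(lib)
#' h <- sampleAssignedAAWS(seed = 2)
#' s <- normalizeSignal(simulateSignal(lib, makeMixture(500, 14, seed = 3), h))
#' q2(q2CrossValidation(s, X, seed = 4))
#' @export
q2CrossValidation <- function(s, X, folds = 10L, seed = NULL,
                              nComponents = NULL, foldAssignments = NULL) {
  y <- .normalizedVector(s)
  X <- .checkCompositionInput(X, length(y))
  n <- length(y)
  if (is.null(foldAssignments)) {
    if (!.isCount(folds) || folds < 2L)
      stop("folds must be an integer >= 2")
    folds <- as.integer(folds)
    if (!is.null(seed)) set.seed(as.integer(seed))
    assign <- sample(rep_len(seq_len(folds), n))
  } else {
    assign <- as.integer(foldAssignments)
    if (length(assign) != n)
      stop("foldAssignments must assign every peptide")
    folds <- max(assign)
  }
  if (min(tabulate(assign, folds)) < 2L)
    stop("every fold needs at least 2 peptides; reduce folds")

  pred <- numeric(n)
  press <- numeric(folds)
  usedK <- integer(folds)
  for (f in seq_len(folds)) {
    te <- assign == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    k <- if (is.null(nComponents)) .plsSelectNcomp(Xtr, ytr)
         else as.integer(nComponents)
    fit <- .plsFit(Xtr, ytr, max(k, 1L))
    k <- min(k, ncol(fit$coefPath))
    pred[te] <- .plsPredict(fit, X[te, , drop = FALSE], k)
    press[f] <- sum((pred[te] - y[te])^2)
    usedK[f] <- k
  }
  new("CvResult",
      q2 = q2Statistic(y, pred),
      foldAssignments = assign,
      perFoldPress = press,
      predictions = setNames(pred, rownames(X)),
      nComponents = usedK)
}

#' Predictive performance statistic
#'
#' The pooled performance
#' `Q2 = 1 - sum((predicted - observed)^2) / sum(observed^2)`, evaluated
#' over left-out observations. Exactly 1 when predictions match the
#' observations, exactly 0 for the all-zero predictor, negative when
#' predictions are worse than predicting zero. The observed values are
#' assumed globally centred (as normalized profiles are), so the
#' denominator approximates total variance.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single number `<= 1` (unbounded below).
#' @examples
#' s <- scale(rnorm(50))[, 1]
#' q2Statistic(s, s)                # 1
#' q2Statistic(s, rep(0, 50))       # 0
#' @export
q2Statistic <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  1 - sum((predicted - observed)^2) / sum(observed^2)
}

#' Secondary-antibody background correction
#'
#' Fluorochrome-coupled polyclonal secondary antibodies bind peptide probes
#' directly; their contribution is removed from measured log intensities by
#' the linear model `log(I) = b0 + b1 * log(I_secondary) + e`, fitted by
#' ordinary least squares (for a single predictor, PLS and OLS coincide).
#' The residuals, centred to zero mean and scaled to unit variance, are the
#' corrected, normalized binding profile used for all further analysis.
#'
#' @param logIntensity Numeric vector of log-transformed measured
#'   intensities.
#' @param logSecondary Numeric vector of log-transformed
#'   secondary-antibody-only intensities (same peptides, same order).
#' @return A list with elements `profile` (normalized [BindingProfile]) and
#'   `model` ([CorrectionModel-class]).
#' @examples
#' set.seed(1)
#' logSec <- rnorm(255)
#' logI <- 1 + 0.5 * logSec + rnorm(255, 0, 0.1)
#' out <- secondaryCorrection(logI, logSec)
#' out$model
#' @export
secondaryCorrection <- function(logIntensity, logSecondary) {
  stopifnot(is.numeric(logIntensity), is.numeric(logSecondary))
  if (length(logIntensity) != length(logSecondary))
    stop("intensity vectors must have equal length")
  if (any(!is.finite(logIntensity)) || any(!is.finite(logSecondary)))
    stop("intensities must be finite")
  if (sd(logSecondary) < 1e-12)
    stop("constant secondary-antibody signal: slope unidentifiable")
  fit <- lm(logIntensity ~ logSecondary)
  res <- unname(stats::residuals(fit))
  if (sd(res) < 1e-12)
    stop("degenerate profile: residuals are constant after correction")
  prof <- BindingProfile(values = setNames((res - mean(res)) / sd(res),
                                           names(logIntensity)),
                         stage = "normalized")
  model <- new("CorrectionModel",
               intercept = unname(coef(fit)[1L]),
               slope = unname(coef(fit)[2L]),
               residuals = res)
  list(profile = prof, model = model)
}

# --- shared input checks -------------------------------------------------

.normalizedVector <- function(s) {
  v <- if (is(s, "BindingProfile")) {
    if (profileStage(s) != "normalized")
      stop("profile must be normalized first (see normalizeSignal())")
    profileValues(s)
  } else if (is.numeric(s)) {
    s
  } else stop("s must be a BindingProfile or a numeric vector")
  if (abs(mean(v)) > 1e-6 || abs(sd(v) - 1) > 1e-6)
    stop("s must be centred to mean 0 and scaled to unit variance")
  v
}

.checkCompositionInput <- function(X, n) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  if (ncol(X) != 20L)
    stop("X must have 20 columns (one per amino acid)")
  if (nrow(X) != n)
    stop("X has ", nrow(X), " rows but the profile has ", n, " values")
  if (!is.null(colnames(X)) && !identical(colnames(X), .AA20))
    stop("X columns must follow the canonical alphabet order")
  X
}
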