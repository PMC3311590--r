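#' @include AllGenerics.R utils.R
NULL

#' PeptideLibrary: a fixed-length random-sequence peptide library
#'
#' An ordered collection of equal-length peptide sequences over the canonical
#' 20-letter amino-acid alphabet, with unique identifiers. The sequence data
#' are held as a [Biostrings::AAStringSet] whose names are the peptide ids.
#'
#' @slot sequences An `AAStringSet` of equal-width sequences with unique
#'   non-empty names.
#'
#' @param sequences Character vector of peptide sequences, or an
#'   `AAStringSet`.
#' @param ids Optional character vector of unique peptide identifiers; taken
#'   from `names(sequences)` when absent, or autogenerated as `pep0001`, ...
#'
#' @return `PeptideLibrary()` returns a validated `PeptideLibrary` object.
#' @seealso [generateLibrary()], [compositionMatrix()], [readLibrary()]
#' @examples
#' lib <- PeptideLibrary(c(p1 = "ACDY", p2 = "WYCA"))
#' peptideLength(lib)
#' peptideSequences(lib)
#' @aliases PeptideLibrary
#' @export PeptideLibrary
#' @exportClass PeptideLibrary
PeptideLibrary <- setClass("PeptideLibrary",
  slots = c(sequences = "AAStringSet"))

setValidity("PeptideLibrary", function(object) {
  seqs <- object@sequences
  if (length(seqs) == 0L)
    return("library must contain at least one peptide")
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("all peptides must have non-empty ids")
  if (anyDuplicated(ids))
    return(paste0("duplicate peptide ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]]
    return(paste0("all sequences must have equal length; offending ids: ",
                  paste(bad, collapse = ", ")))
  }
  counts <- Biostrings::letterFrequency(seqs, letters = .AA20)
  bad <- rowSums(counts) != w
  if (any(bad))
    return(paste0("sequences contain residues outside the 20-letter ",
                  "alphabet; offending ids: ",
                  paste(ids[bad], collapse = ", ")))
  TRUE
})

#' @rdname PeptideLibrary-class
#' @export
setMethod("initialize", "PeptideLibrary", function(.Object, sequences, ids = NULL, ...) {
  if (missing(sequences)) return(callNextMethod(.Object, ...))
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  if (!is.null(ids)) {
    names(sequences) <- as.character(ids)
  } else if (is.null(names(sequences))) {
    names(sequences) <- sprintf("pep%04d", seq_along(sequences))
  }
  callNextMethod(.Object, sequences = sequences, ...)
})

#' @rdname PeptideLibrary-class
#' @export
setMethod("length", "PeptideLibrary", function(x) length(x@sequences))

#' @rdname PeptideLibrary-class
#' @export
setMethod("peptideIds", "PeptideLibrary", function(x) names(x@sequences))

#' @rdname PeptideLibrary-class
#' @export
setMethod("peptideSequences", "PeptideLibrary",
          function(x) setNames(as.character(x@sequences), names(x@sequences)))

#' @rdname PeptideLibrary-class
#' @export
setMethod("peptideLength", "PeptideLibrary",
          function(x) Biostrings::width(x@sequences)[1L])

setMethod("show", "PeptideLibrary", function(object) {
  cat("PeptideLibrary of", length(object), "peptides, length",
      peptideLength(object), "\n")
  n <- min(3L, length(object))
  s <- peptideSequences(object)[seq_len(n)]
  for (i in seq_len(n)) cat(" ", names(s)[i], s[[i]], "\n")
  if (length(object) > n) cat("  ...\n")
})

#' AAWS containers: assigned and estimated amino-acid-associated weights
#'
#' `AssignedAAWS` holds the generative 20-vector `h` of per-residue binding
#' strengths used by the simulator (each component in `[0, 1]`).
#' `AAWSEstimate` holds a fitted 20-vector `w` of amino-acid-associated
#' weights from the composition-only regression, together with the regression
#' intercept, residuals, and the number of PLS components used.
#' Both are indexed by the canonical alphabet ([aminoAcidAlphabet()]).
#'
#' @slot weights Named numeric 20-vector in canonical alphabet order.
#' @slot intercept Fitted intercept (centring offset) of the regression.
#' @slot residuals Residual vector, one value per peptide.
#' @slot nComponents Number of PLS components used for the reported weights.
#' @slot fittedOn Free-text identifier of the profile the estimate was
#'   fitted on.
#'
#' @param weights Numeric 20-vector, optionally named by amino acid.
#' @return Constructors return validated objects; `aawsWeights()` returns the
#'   named numeric 20-vector.
#' @seealso [sampleAssignedAAWS()], [fitAAWS()]
#' @examples
#' h <- AssignedAAWS(seq(0.025, 1, length.out = 20))
#' aawsWeights(h)[c("A", "Y")]
#' @name AAWS-classes
#' @aliases AssignedAAWS AAWSEstimate
#' @export AssignedAAWS
#' @exportClass AssignedAAWS
AssignedAAWS <- setClass("AssignedAAWS", slots = c(weights = "numeric"))

setValidity("AssignedAAWS", function(object) {
  w <- object@weights
  if (length(w) != 20L || !identical(names(w), .AA20))
    return("weights must be a 20-vector named by the canonical alphabet")
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    return("assigned weights must lie in [0, 1]")
  TRUE
})

setMethod("initialize", "AssignedAAWS", function(.Object, weights, ...) {
  if (missing(weights)) return(callNextMethod(.Object, ...))
  callNextMethod(.Object, weights = .canonical20(weights), ...)
})

#' @rdname AAWS-classes
#' @export
setMethod("aawsWeights", "AssignedAAWS", function(x) x@weights)

setMethod("show", "AssignedAAWS", function(object) {
  cat("AssignedAAWS (h): 20 weights in [0, 1]\n")
  print(round(object@weights, 3))
})

#' @rdname AAWS-classes
#' @export AAWSEstimate
#' @exportClass AAWSEstimate
AAWSEstimate <- setClass("AAWSEstimate",
  slots = c(weights = "numeric", intercept = "numeric",
            residuals = "numeric", nComponents = "integer",
            fittedOn = "character"))

setValidity("AAWSEstimate", function(object) {
  if (length(object@weights) != 20L ||
      !identical(names(object@weights), .AA20))
    return("weights must be a 20-vector named by the canonical alphabet")
  if (length(object@intercept) != 1L)
    return("intercept must be a single number")
  if (length(object@nComponents) != 1L || object@nComponents < 1L)
    return("nComponents must be a positive integer")
  TRUE
})

#' @rdname AAWS-classes
#' @export
setMethod("aawsWeights", "AAWSEstimate", function(x) x@weights)

#' @rdname AAWS-classes
#' @param object An `AAWSEstimate`.
#' @param ... Ignored.
#' @export
setMethod("residuals", "AAWSEstimate", function(object, ...) object@residuals)

setMethod("show", "AAWSEstimate", function(object) {
  cat("AAWSEstimate:", object@nComponents, "PLS component(s), fitted on",
      object@fittedOn, "\n")
  print(round(object@weights, 3))
})

#' AntibodyMixture: binding-site vectors and a concentration simplex
#'
#' A mixture of `nAb` simulated antibodies. Each antibody binding site is a
#' unit-Euclidean-norm numeric vector of length `l` (one binding strength per
#' peptide position); concentrations are non-negative and sum to one.
#'
#' @slot bindingSites `nAb x l` numeric matrix; every row has unit 2-norm.
#' @slot concentrations Numeric `nAb`-vector on the unit simplex.
#'
#' @param bindingSites Numeric matrix of binding-site vectors (rows).
#' @param concentrations Numeric vector of concentrations; defaults to
#'   uniform.
#' @return A validated `AntibodyMixture`.
#' @seealso [makeMixture()], [sampleAntibody()], [simulateSignal()]
#' @examples
#' a <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
#' mix <- AntibodyMixture(a, c(0.5, 0.5))
#' concentrations(mix)
#' @aliases AntibodyMixture
#' @export AntibodyMixture
#' @exportClass AntibodyMixture
AntibodyMixture <- setClass("AntibodyMixture",
  slots = c(bindingSites = "matrix", concentrations = "numeric"))

setValidity("AntibodyMixture", function(object) {
  A <- object@bindingSites
  cc <- object@concentrations
  if (!is.numeric(A) || nrow(A) < 1L)
    return("bindingSites must be a numeric matrix with >= 1 row")
  if (length(cc) != nrow(A))
    return("one concentration per antibody required")
  if (any(abs(sqrt(rowSums(A^2)) - 1) > 1e-8))
    return("every binding-site vector must have unit Euclidean norm")
  if (any(cc < 0) || abs(sum(cc) - 1) > 1e-8)
    return("concentrations must be non-negative and sum to 1")
  TRUE
})

setMethod("initialize", "AntibodyMixture",
          function(.Object, bindingSites, concentrations = NULL, ...) {
  if (missing(bindingSites)) return(callNextMethod(.Object, ...))
  if (is.null(concentrations))
    concentrations <- rep(1 / nrow(bindingSites), nrow(bindingSites))
  callNextMethod(.Object, bindingSites = bindingSites,
                 concentrations = concentrations, ...)
})

#' @rdname AntibodyMixture-class
#' @export
setMethod("length", "AntibodyMixture", function(x) nrow(x@bindingSites))

#' @rdname AntibodyMixture-class
#' @export
setMethod("bindingSites", "AntibodyMixture", function(x) x@bindingSites)

#' @rdname AntibodyMixture-class
#' @export
setMethod("concentrations", "AntibodyMixture", function(x) x@concentrations)

setMethod("show", "AntibodyMixture", function(object) {
  cat("AntibodyMixture:", length(object), "antibodies, binding-site length",
      ncol(object@bindingSites), "\n")
  cmax <- max(object@concentrations)
  cat("  concentrations: max", signif(cmax, 4), "min",
      signif(min(object@concentrations), 4), "\n")
})

#' ThermoParams: thermodynamic constants of the association model
#'
#' Constants mapping the antibody-peptide binding association `y` to the
#' equilibrium association constant `K = exp((beta0 + beta1 * y) / (R * T))`.
#' The defaults (`R = 8.314472`, `T = 298.15` K, `beta0 = 0`,
#' `beta1 = R * T`) reduce this to `K = exp(y)`.
#'
#' @slot gasConstant Gas constant `R` (J mol^-1 K^-1), > 0.
#' @slot temperature Absolute temperature `T` (K), > 0.
#' @slot beta0,beta1 Affine coefficients of the standard free-energy change.
#'
#' @param gasConstant,temperature,beta0,beta1 See slots.
#' @return `thermoParams()` returns a validated `ThermoParams` object.
#' @examples
#' thermoParams()                      # defaults: K = exp(y)
#' thermoParams(beta1 = 0)             # association-independent K
#' @aliases ThermoParams
#' @export
#' @exportClass ThermoParams
thermoParams <- function(gasConstant = 8.314472, temperature = 273.15 + 25,
                         beta0 = 0, beta1 = gasConstant * temperature) {
  new("ThermoParams", gasConstant = gasConstant, temperature = temperature,
      beta0 = beta0, beta1 = beta1)
}

setClass("ThermoParams",
  slots = c(gasConstant = "numeric", temperature = "numeric",
            beta0 = "numeric", beta1 = "numeric"))

setValidity("ThermoParams", function(object) {
  if (length(object@gasConstant) != 1L || object@gasConstant <= 0)
    return("gasConstant must be a single positive number")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    return("temperature must be a single positive number")
  if (length(object@beta0) != 1L || length(object@beta1) != 1L)
    return("beta0 and beta1 must be single numbers")
  TRUE
})

setMethod("show", "ThermoParams", function(object) {
  cat("ThermoParams: R =", object@gasConstant, ", T =", object@temperature,
      "K, beta0 =", object@beta0, ", beta1 =", object@beta1, "\n")
})

#' BindingProfile: a signal-intensity vector over the peptide library
#'
#' One value per peptide, tagged with its processing stage:
#' `"raw_fraction"` (Langmuir bound fraction, strictly inside `(0, 1)`),
#' `"logged"` (log-transformed) or `"normalized"` (log-transformed,
#' mean-centred, unit variance).
#'
#' @slot values Named numeric vector (names are peptide ids).
#' @slot stage One of `"raw_fraction"`, `"logged"`, `"normalized"`.
#'
#' @param values Numeric vector of signal values.
#' @param stage Processing stage string.
#' @return A validated `BindingProfile`.
#' @seealso [simulateSignal()], [applyNoise()], [normalizeSignal()]
#' @aliases BindingProfile
#' @export BindingProfile
#' @exportClass BindingProfile
BindingProfile <- setClass("BindingProfile",
  slots = c(values = "numeric", stage = "character"))

setValidity("BindingProfile", function(object) {
  v <- object@values
  st <- object@stage
  if (length(st) != 1L ||
      !st %in% c("raw_fraction", "logged", "normalized"))
    return("stage must be one of raw_fraction, logged, normalized")
  if (length(v) < 1L || any(!is.finite(v)))
    return("values must be finite and non-empty")
  if (st == "raw_fraction" && (any(v <= 0) || any(v >= 1)))
    return("raw_fraction values must lie strictly in (0, 1)")
  if (st == "normalized" &&
      (abs(mean(v)) > 1e-6 || abs(sd(v) - 1) > 1e-6))
    return("normalized values must have mean 0 and unit sd")
  TRUE
})

#' @rdname BindingProfile-class
#' @export
setMethod("length", "BindingProfile", function(x) length(x@values))

#' @rdname BindingProfile-class
#' @export
setMethod("profileValues", "BindingProfile", function(x) x@values)

#' @rdname BindingProfile-class
#' @export
setMethod("profileStage", "BindingProfile", function(x) x@stage)

setMethod("show", "BindingProfile", function(object) {
  cat("BindingProfile (", object@stage, "): ", length(object),
      " peptides\n", sep = "")
  cat("  range:", signif(min(object@values), 4), "..",
      signif(max(object@values), 4), "\n")
})

#' CvResult: cross-validated predictive performance
#'
#' Result of k-fold cross-validation of the composition-only regression:
#' the pooled predictive performance `Q2 = 1 - PRESS / TSS` over all
#' left-out peptides, the fold assignment, per-fold prediction error sums,
#' and the pooled out-of-fold predictions.
#'
#' @slot q2 Predictive performance (`<= 1`; can be negative).
#' @slot foldAssignments Integer fold id per peptide.
#' @slot perFoldPress Per-fold sum of squared prediction errors.
#' @slot predictions Out-of-fold predicted values, one per peptide.
#' @slot nComponents Integer vector: PLS components used per fold.
#'
#' @seealso [q2CrossValidation()]
#' @aliases CvResult
#' @exportClass CvResult
setClass("CvResult",
  slots = c(q2 = "numeric", foldAssignments = "integer",
            perFoldPress = "numeric", predictions = "numeric",
            nComponents = "integer"))

setValidity("CvResult", function(object) {
  if (length(object@q2) != 1L || object@q2 > 1 + 1e-12)
    return("q2 must be a single value <= 1")
  if (length(object@predictions) != length(object@foldAssignments))
    return("one prediction per peptide required")
  TRUE
})

#' @rdname CvResult-class
#' @export
setMethod("q2", "CvResult", function(x) x@q2)

setMethod("show", "CvResult", function(object) {
  cat("CvResult:", length(object@perFoldPress), "folds, Q2 =",
      round(object@q2, 4), "\n")
})

#' CorrectionModel: secondary-antibody background correction fit
#'
#' Linear model `log(I) = b0 + b1 * log(I_secondary) + residual` used to
#' remove the signal contributed by the fluorochrome-coupled polyclonal
#' secondary antibody binding directly to peptide probes. The centred and
#' scaled residuals are the corrected binding profile.
#'
#' @slot intercept,slope Fitted coefficients `b0`, `b1`.
#' @slot residuals Raw (unscaled) residuals.
#' @seealso [secondaryCorrection()]
#' @aliases CorrectionModel
#' @exportClass CorrectionModel
setClass("CorrectionModel",
  slots = c(intercept = "numeric", slope = "numeric", residuals = "numeric"))

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel: log(I) =", round(object@intercept, 4), "+",
      round(object@slope, 4), "* log(I_sec) + e\n")
})

#' SweepResult: antibody-diversity sweep
#'
#' Per grid point (number of antibodies in the mixture) and replicate:
#' cross-validated Q2 and recovery correlation of the assigned weights, plus
#' pairwise Pearson correlations among the replicate AAWS estimates.
#'
#' @slot nAbGrid Integer vector of mixture sizes.
#' @slot q2Samples,hRecoverySamples Lists (one numeric vector per grid
#'   point, one value per replicate).
#' @slot pairwiseRSamples List (one numeric vector per grid point, one value
#'   per unordered pair of replicates).
#' @seealso [diversitySweep()]
#' @aliases SweepResult
#' @exportClass SweepResult
setClass("SweepResult",
  slots = c(nAbGrid = "integer", q2Samples = "list",
            pairwiseRSamples = "list", hRecoverySamples = "list"))

setValidity("SweepResult", function(object) {
  k <- length(object@nAbGrid)
  if (length(object@q2Samples) != k ||
      length(object@pairwiseRSamples) != k ||
      length(object@hRecoverySamples) != k)
    return("one sample vector per grid point required")
  if (length(unique(lengths(object@q2Samples))) > 1L)
    return("replicate counts must be equal across grid points")
  r <- unlist(object@pairwiseRSamples)
  if (length(r) && (any(r < -1 - 1e-9) || any(r > 1 + 1e-9)))
    return("pairwise correlations must lie in [-1, 1]")
  TRUE
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over n_Ab =", paste(object@nAbGrid, collapse = ", "),
      "\n  median Q2:",
      paste(signif(vapply(object@q2Samples, median, 0), 3), collapse = ", "),
      "\n")
})

#' @describeIn SweepResult-class Long-format table with columns `n_ab`,
#'   `metric` (`q2`, `h_recovery` or `pairwise_r`), `index` (replicate or
#'   pair index) and `value`.
#' @param x,row.names,optional,... See [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "SweepResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  blocks <- lapply(seq_along(x@nAbGrid), function(i) {
    rbind(
      data.frame(n_ab = x@nAbGrid[i], metric = "q2",
                 index = seq_along(x@q2Samples[[i]]),
                 value = x@q2Samples[[i]]),
      data.frame(n_ab = x@nAbGrid[i], metric = "h_recovery",
                 index = seq_along(x@hRecoverySamples[[i]]),
                 value = x@hRecoverySamples[[i]]),
      data.frame(n_ab = x@nAbGrid[i], metric = "pairwise_r",
                 index = seq_along(x@pairwiseRSamples[[i]]),
                 value = x@pairwiseRSamples[[i]]))
  })
  do.call(rbind, blocks)
})

#' DominanceResult: one noise/dominance simulation case
#'
#' Replicate Q2 and pairwise-AAWS-correlation samples for one of the four
#' canonical cases run by [dominanceExperiment()]:
#' I (`sigma = 0`, factor 1), II (`sigma = 0.01`, factor 1),
#' III (`sigma = 0.01`, factor 10), IV (`sigma = 0.01`, factor 1000).
#'
#' @slot case Case label (`"I"`, `"II"`, `"III"`, `"IV"`).
#' @slot sigma Multiplicative noise standard deviation.
#' @slot dominanceFactor Concentration multiplier of the dominant antibody.
#' @slot q2Samples,pairwiseRSamples Numeric sample vectors.
#' @aliases DominanceResult
#' @exportClass DominanceResult
setClass("DominanceResult",
  slots = c(case = "character", sigma = "numeric",
            dominanceFactor = "numeric", q2Samples = "numeric",
            pairwiseRSamples = "numeric"))

setMethod("show", "DominanceResult", function(object) {
  cat("DominanceResult case ", object@case, " (sigma = ", object@sigma,
      ", factor = ", object@dominanceFactor, "): median Q2 = ",
      signif(median(object@q2Samples), 4), "\n", sep = "")
})

#' @describeIn DominanceResult-class Long-format table with columns `case`,
#'   `metric`, `index`, `value`.
#' @param x,row.names,optional,... See [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "DominanceResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  rbind(
    data.frame(case = x@case, metric = "q2",
               index = seq_along(x@q2Samples), value = x@q2Samples),
    data.frame(case = x@case, metric = "pairwise_r",
               index = seq_along(x@pairwiseRSamples),
               value = x@pairwiseRSamples))
})

#' PcaResult: principal component analysis of a set of AAWS
#'
#' Column-centred PCA of an `n x 20` matrix of AAWS vectors (one row per
#' sample), truncated to the first `k` components.
#'
#' @slot scores `n x k` score matrix.
#' @slot loadings `20 x k` loading matrix.
#' @slot varianceExplained Length-`k` vector of variance fractions,
#'   non-increasing, each in `[0, 1]`, summing to at most 1.
#' @seealso [pcaAAWS()]
#' @aliases PcaResult
#' @exportClass PcaResult
setClass("PcaResult",
  slots = c(scores = "matrix", loadings = "matrix",
            varianceExplained = "numeric"))

setValidity("PcaResult", function(object) {
  ve <- object@varianceExplained
  if (any(ve < -1e-12) || any(ve > 1 + 1e-12) || sum(ve) > 1 + 1e-9)
    return("variance fractions must lie in [0, 1] and sum to <= 1")
  if (is.unsorted(rev(ve), strictly = FALSE))
    return("variance fractions must be non-increasing")
  if (ncol(object@scores) != length(ve) ||
      ncol(object@loadings) != length(ve))
    return("scores, loadings and varianceExplained must agree on k")
  TRUE
})

setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", nrow(object@scores), "samples,",
      length(object@varianceExplained), "components; variance explained:",
      paste(signif(object@varianceExplained, 3), collapse = ", "), "\n")
})
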