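#' Sample assigned amino-acid-associated weights
#'
#' Draws the generative 20-vector `h`: one i.i.d. `U[0, 1]` binding strength
#' per amino acid. These weights define the position-dependent peptide
#' encoding used by the binding simulator; their recovery by the
#' composition-only regression is the model's identifiability check.
#'
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An [AssignedAAWS].
#' @examples
#' h <- sampleAssignedAAWS(seed = 1)
#' range(aawsWeights(h))
#' @export
sampleAssignedAAWS <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  AssignedAAWS(runif(20L))
}

#' Encode a peptide as a vector of assigned weights
#'
#' Maps a sequence of length `l` to the numeric `l`-vector
#' `p[j] = h[residue at position j]`. The encoding is position-dependent:
#' permuting the sequence permutes `p` identically.
#'
#' @param sequence A single peptide sequence (character scalar).
#' @param h An [AssignedAAWS] or a named numeric 20-vector.
#' @return Numeric vector of length `nchar(sequence)`.
#' @examples
#' h <- sampleAssignedAAWS(seed = 1)
#' encodePeptide("ACDY", h)
#' @export
encodePeptide <- function(sequence, h) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  hw <- if (is(h, "AssignedAAWS")) aawsWeights(h) else .canonical20(h)
  res <- strsplit(sequence, "")[[1L]]
  idx <- match(res, .AA20)
  if (anyNA(idx))
    stop("unknown residue(s) in sequence: ",
         paste(unique(res[is.na(idx)]), collapse = ", "))
  unname(hw[idx])
}

# Encode a whole library as an nPep x l matrix of h-values.
.encodeLibrary <- function(lib, h) {
  hw <- if (is(h, "AssignedAAWS")) aawsWeights(h) else .canonical20(h)
  mat <- do.call(rbind, strsplit(unname(peptideSequences(lib)), ""))
  idx <- match(mat, .AA20)
  if (anyNA(idx)) stop("library contains unknown residues")
  matrix(hw[idx], nrow = nrow(mat), ncol = ncol(mat),
         dimnames = list(peptideIds(lib), NULL))
}

#' Sample a random antibody binding-site vector
#'
#' Components are drawn i.i.d. `U[-1, 1]` and the vector is scaled to unit
#' Euclidean norm. The (probability-zero) all-zero draw is resampled.
#'
#' @param l Binding-site length (matches the peptide length).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric `l`-vector with `sum(a^2) == 1`.
#' @examples
#' a <- sampleAntibody(14, seed = 3)
#' sum(a^2)
#' @export
sampleAntibody <- function(l, seed = NULL) {
  if (!.isCount(l)) stop("l must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  repeat {
    a <- runif(l, -1, 1)
    n2 <- sqrt(sum(a^2))
    if (n2 > 0) return(a / n2)
  }
}

#' Assemble an antibody mixture with optional dominance
#'
#' Samples `nAb` unit-norm binding-site vectors and assigns uniform baseline
#' concentrations `1 / nAb`. If `dominanceFactor > 1`, the concentration
#' weight of the dominant antibody (the supplied `dominant` vector, placed
#' first, or the first sampled antibody) is multiplied by the factor and the
#' concentration vector renormalised to sum to one, so the simplex
#' constraint is preserved. For example, `nAb = 16000` with factor 1000
#' gives the dominant antibody a concentration of `1000 / (1000 + 15999)`.
#'
#' @param nAb Number of antibodies (>= 1).
#' @param l Binding-site length.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param dominanceFactor Concentration multiplier (>= 1) of the dominant
#'   antibody.
#' @param dominant Optional numeric `l`-vector used as the dominant
#'   antibody's binding site (normalised to unit norm if needed). When
#'   supplied, only `nAb - 1` background antibodies are sampled.
#' @return An [AntibodyMixture].
#' @examples
#' mix <- makeMixture(4, 14, seed = 1)
#' concentrations(mix)
#' makeMixture(2, 14, seed = 1, dominanceFactor = 3)  # conc (0.75, 0.25)
#' @export
makeMixture <- function(nAb, l, seed = NULL, dominanceFactor = 1,
                        dominant = NULL) {
  if (!.isCount(nAb)) stop("nAb must be a positive integer")
  if (!.isCount(l)) stop("l must be a positive integer")
  if (!is.numeric(dominanceFactor) || dominanceFactor < 1)
    stop("dominanceFactor must be >= 1")
  if ((dominanceFactor > 1 || !is.null(dominant)) && nAb < 2L)
    stop("dominance requires a mixture of at least 2 antibodies")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nAb <- as.integer(nAb)

  nBackground <- if (is.null(dominant)) nAb else nAb - 1L
  A <- matrix(runif(nBackground * l, -1, 1), nBackground, l)
  A <- A / sqrt(rowSums(A^2))
  if (!is.null(dominant)) {
    stopifnot(is.numeric(dominant), length(dominant) == l)
    dom <- dominant / sqrt(sum(dominant^2))
    A <- rbind(dom, A, deparse.level = 0)
  }
  cc <- rep(1, nAb)
  cc[1L] <- dominanceFactor
  AntibodyMixture(A, cc / sum(cc))
}

#' Binding association between an antibody and an encoded peptide
#'
#' The dot product `y = a . p` of a unit-norm binding-site vector with an
#' encoded peptide. By Cauchy-Schwarz `|y| <= |p| <= sqrt(l)` since the
#' encoding components lie in `[0, 1]`.
#'
#' @param a Antibody binding-site vector.
#' @param p Encoded peptide vector ([encodePeptide()]).
#' @return A single number.
#' @examples
#' bindingAssociation(c(1, 0), c(0.2, 0.9))  # 0.2
#' @export
bindingAssociation <- function(a, p) {
  if (length(a) != length(p))
    stop("antibody and peptide vectors must have equal length")
  sum(a * p)
}

#' Thermodynamic association constant
#'
#' `K = exp((beta0 + beta1 * y) / (R * T))`, interpreting the binding
#' association `y` as negatively proportional to the standard Gibbs free
#' energy change. With the default [thermoParams()] (`beta0 = 0`,
#' `beta1 = R * T`) this reduces to `K = exp(y)`.
#'
#' @param y Binding association value(s).
#' @param theta A [ThermoParams-class] object.
#' @return Positive association constant(s), same length as `y`.
#' @examples
#' associationConstant(0)  # 1
#' associationConstant(1)  # exp(1)
#' @export
associationConstant <- function(y, theta = thermoParams()) {
  stopifnot(is(theta, "ThermoParams"))
  K <- exp((theta@beta0 + theta@beta1 * y) /
             (theta@gasConstant * theta@temperature))
  if (any(!is.finite(K)))
    stop("association constant overflows for the given y and parameters")
  K
}

#' Simulate Langmuir binding of an antibody mixture to a peptide library
#'
#' For each peptide `i` and antibody `k`, the association is the dot product
#' of the antibody binding site with the `h`-encoded peptide; the association
#' constant is `K[i,k] = exp((beta0 + beta1 * y[i,k]) / (R * T))`. The
#' simulated signal is the equilibrium Langmuir bound fraction
#' \deqn{S_i = \frac{\sum_k [Ab]_k K_{i,k}}{1 + \sum_k [Ab]_k K_{i,k}},}
#' strictly between 0 and 1 and monotone increasing in every `K[i,k]`.
#'
#' @param lib A [PeptideLibrary].
#' @param mix An [AntibodyMixture] whose binding-site length equals the
#'   peptide length.
#' @param h An [AssignedAAWS] (or named 20-vector) of per-residue weights.
#' @param theta A [ThermoParams-class] object.
#' @return A [BindingProfile] at stage `"raw_fraction"`, named by peptide id.
#' @examples
#' lib <- generateLibrary(20, 14, seed = 1)
#' h <- sampleAssignedAAWS(seed = 2)
#' mix <- makeMixture(5, 14, seed = 3)
#' profileValues(simulateSignal(lib, mix, h))[1:3]
#' @export
simulateSignal <- function(lib, mix, h, theta = thermoParams()) {
  stopifnot(is(lib, "PeptideLibrary"), is(mix, "AntibodyMixture"))
  P <- .encodeLibrary(lib, h)
  A <- bindingSites(mix)
  if (ncol(A) != ncol(P))
    stop("antibody binding-site length (", ncol(A),
         ") does not match peptide length (", ncol(P), ")")
  Y <- P %*% t(A)
  K <- associationConstant(Y, theta)
  load <- drop(K %*% concentrations(mix))
  BindingProfile(values = setNames(load / (1 + load), peptideIds(lib)),
                 stage = "raw_fraction")
}

#' Apply multiplicative Gaussian noise to a raw binding profile
#'
#' Each bound fraction is perturbed as `S * (1 + e)` with
#' `e ~ N(0, sigma^2)` i.i.d., before any log transformation. A draw that
#' would push a value out of the open interval `(0, 1)` is redrawn (rather
#' than truncated) so the subsequent log transform stays defined; at the
#' default `sigma = 0.01` this essentially never triggers.
#'
#' @param profile A [BindingProfile] at stage `"raw_fraction"`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [BindingProfile] at stage `"raw_fraction"`.
#' @examples
#' lib <- generateLibrary(20, 14, seed = 1)
#' s <- simulateSignal(lib, makeMixture(5, 14, seed = 3),
#'                     sampleAssignedAAWS(seed = 2))
#' noisy <- applyNoise(s, 0.01, seed = 4)
#' @export
applyNoise <- function(profile, sigma, seed = NULL) {
  stopifnot(is(profile, "BindingProfile"))
  if (profileStage(profile) != "raw_fraction")
    stop("noise is applied to raw_fraction profiles, before the log")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(profile)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- profileValues(profile)
  out <- v * (1 + rnorm(length(v), 0, sigma))
  bad <- which(out <= 0 | out >= 1)
  while (length(bad)) {
    out[bad] <- v[bad] * (1 + rnorm(length(bad), 0, sigma))
    bad <- bad[out[bad] <= 0 | out[bad] >= 1]
  }
  BindingProfile(values = out, stage = "raw_fraction")
}

#' Normalise a binding profile
#'
#' Log-transforms (natural log) a raw bound-fraction profile, then centres
#' to zero mean and scales to unit variance. An already log-transformed
#' profile is centred and scaled only.
#'
#' @param profile A [BindingProfile] at stage `"raw_fraction"` or
#'   `"logged"`.
#' @return A [BindingProfile] at stage `"normalized"`.
#' @examples
#' lib <- generateLibrary(20, 14, seed = 1)
#' s <- simulateSignal(lib, makeMixture(5, 14, seed = 3),
#'                     sampleAssignedAAWS(seed = 2))
#' z <- normalizeSignal(s)
#' c(mean(profileValues(z)), sd(profileValues(z)))
#' @export
normalizeSignal <- function(profile) {
  stopifnot(is(profile, "BindingProfile"))
  v <- switch(profileStage(profile),
    raw_fraction = log(profileValues(profile)),
    logged = profileValues(profile),
    stop("profile is already normalized"))
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate profile: constant after log transform")
  BindingProfile(values = (v - mean(v)) / s, stage = "normalized")
}
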