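# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
# Every 20-vector and 20-column object in the package is ordered this way.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The canonical amino-acid alphabet
#'
#' Returns the 20 proteinogenic one-letter codes in the fixed order used for
#' every 20-vector (assigned and estimated AAWS) and every 20-column object
#' (composition matrices, property-scale tables) in the package: alphabetical
#' by one-letter code, `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @return Character vector of length 20.
#' @examples
#' aminoAcidAlphabet()
#' @export
aminoAcidAlphabet <- function() .AA20

# Derive n reproducible sub-seeds from one master seed. Used so that each
# source of randomness (library, h, antibodies, noise, folds) has its own
# named stream and experiments can vary one source at a time.
.deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Validate a named 20-vector in canonical order; reorders a fully named
# vector, names an unnamed one.
.canonical20 <- function(x, what = "weights") {
  if (!is.numeric(x) || length(x) != 20L)
    stop(what, " must be a numeric vector of length 20", call. = FALSE)
  if (is.null(names(x))) {
    names(x) <- .AA20
  } else {
    if (!setequal(names(x), .AA20))
      stop(what, " names must be the 20 amino-acid one-letter codes",
           call. = FALSE)
    x <- x[.AA20]
  }
  x
}
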