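#' Generate a random-sequence peptide library
#'
#' Draws `nPep` sequences of length `l`, each residue sampled uniformly from
#' the 20 proteinogenic amino acids, under the constraint that no residue
#' occurs three or more times consecutively. The constraint is enforced
#' position by position: any draw that would create a run of three is
#' resampled, which preserves near-uniform residue marginals and costs
#' O(`l`) per peptide.
#'
#' @param nPep Number of peptides (positive integer).
#' @param l Peptide length (positive integer).
#' @param seed Integer seed; a fixed seed reproduces the library exactly.
#'   `NULL` uses the current RNG stream.
#' @param unique Logical; if `TRUE`, resample duplicated sequences until all
#'   are distinct. Duplicates are allowed by default.
#'
#' @return A [PeptideLibrary] with ids `pep0001`, `pep0002`, ...
#' @examples
#' lib <- generateLibrary(255, 14, seed = 7)
#' length(lib)
#' any(grepl("(.)\\1\\1", peptideSequences(lib)))  # no runs of three
#' @export
generateLibrary <- function(nPep, l, seed = NULL, unique = FALSE) {
  if (!.isCount(nPep)) stop("nPep must be a positive integer")
  if (!.isCount(l)) stop("l must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nPep <- as.integer(nPep)
  l <- as.integer(l)
  if (isTRUE(unique) && log(nPep) > l * log(20))
    stop("cannot draw ", nPep, " unique sequences of length ", l)

  draw <- function(n) {
    m <- matrix(sample(.AA20, n * l, replace = TRUE), n, l)
    if (l >= 3L) for (j in 3:l) {
      bad <- which(m[, j] == m[, j - 1L] & m[, j - 1L] == m[, j - 2L])
      while (length(bad)) {
        m[bad, j] <- sample(.AA20, length(bad), replace = TRUE)
        bad <- bad[m[bad, j] == m[bad, j - 1L]]
      }
    }
    apply(m, 1L, paste0, collapse = "")
  }

  seqs <- draw(nPep)
  if (isTRUE(unique)) {
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- draw(length(dup))
    }
  }
  PeptideLibrary(seqs, ids = sprintf("pep%04d", seq_len(nPep)))
}

#' Amino-acid composition matrix of a peptide library
#'
#' Counts the occurrences of each of the 20 amino acids in each peptide,
#' giving an `nPep x 20` integer matrix whose columns follow the canonical
#' alphabet order and whose rows sum to the peptide length. The matrix
#' deliberately discards all positional information.
#'
#' @param lib A [PeptideLibrary], or a character vector of equal-length
#'   sequences (optionally named by peptide id).
#'
#' @return Integer matrix with peptide ids as row names and one-letter amino
#'   acid codes as column names.
#' @examples
#' X <- compositionMatrix(generateLibrary(255, 14, seed = 7))
#' dim(X)              # 255 x 20
#' all(rowSums(X) == 14)
#' @export
compositionMatrix <- function(lib) {
  if (is.character(lib)) lib <- PeptideLibrary(lib)
  if (!is(lib, "PeptideLibrary"))
    stop("lib must be a PeptideLibrary or a character vector")
  X <- Biostrings::letterFrequency(lib@sequences, letters = .AA20)
  storage.mode(X) <- "integer"
  rownames(X) <- peptideIds(lib)
  colnames(X) <- .AA20
  X
}

#' Read and write peptide libraries
#'
#' Libraries are stored either as FASTA (the first whitespace-delimited
#' header token is the peptide id) or as 2-column tab-separated text with a
#' `id<TAB>sequence` header. `readLibrary(writeLibrary(lib))` reproduces
#' `lib` exactly, order included. Files failing the library invariants
#' (ragged lengths, duplicate ids, non-canonical residues, empty file) raise
#' an error naming the offending peptides.
#'
#' @param path File path.
#' @param format `"fasta"`, `"tabular"`, or `"auto"` (by file extension:
#'   `.fa`/`.fasta` is FASTA, anything else tabular).
#' @param lib A [PeptideLibrary].
#'
#' @return `readLibrary()` returns a [PeptideLibrary]; `writeLibrary()`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLibrary(generateLibrary(10, 14, seed = 1), tf)
#' length(readLibrary(tf))
#' @export
readLibrary <- function(path, format = c("auto", "fasta", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE))
      "fasta" else "tabular"
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) stop("empty library file: ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(PeptideLibrary(seqs))
  }
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (nrow(tab) == 0L) stop("empty library file: ", path)
  if (ncol(tab) < 2L)
    stop("tabular library must have columns id and sequence")
  PeptideLibrary(tab[[2L]], ids = tab[[1L]])
}

#' @rdname readLibrary
#' @export
writeLibrary <- function(lib, path, format = c("auto", "fasta", "tabular")) {
  stopifnot(is(lib, "PeptideLibrary"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE))
      "fasta" else "tabular"
  if (format == "fasta") {
    Biostrings::writeXStringSet(lib@sequences, filepath = path)
  } else {
    tab <- data.frame(id = peptideIds(lib),
                      sequence = unname(peptideSequences(lib)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export a composition matrix as tab-separated text
#'
#' Writes the matrix with a `peptide_id` first column and one column per
#' amino-acid letter.
#'
#' @param X Composition matrix from [compositionMatrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCompositionMatrix <- function(X, path) {
  tab <- data.frame(peptide_id = rownames(X), X, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
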