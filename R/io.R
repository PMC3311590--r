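#' Read a per-sample intensity table
#'
#' Reads tab-separated text with a header and columns `peptide_id`,
#' `intensity` and optionally `secondary_intensity`. When a library is
#' supplied the rows are re-aligned to the library's peptide order by id;
#' missing or extra ids raise an error listing them. Non-numeric
#' intensities are reported with their row number.
#'
#' @param path File path.
#' @param lib Optional [PeptideLibrary] to align against.
#' @return A list with `intensity` (named numeric vector) and `secondary`
#'   (named numeric vector or `NULL`).
#' @seealso [writeProfileTable()]
#' @export
readIntensityTable <- function(path, lib = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (nrow(tab) == 0L) stop("empty intensity table: ", path)
  need <- c("peptide_id", "intensity")
  if (!all(need %in% colnames(tab)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  ids <- tab$peptide_id
  if (anyDuplicated(ids))
    stop("duplicate peptide ids in intensity table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  asNum <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad))
      stop("non-numeric ", name, " at row(s) ",
           paste(bad, collapse = ", "))
    x
  }
  intensity <- setNames(asNum(tab$intensity, "intensity"), ids)
  secondary <- if ("secondary_intensity" %in% colnames(tab))
    setNames(asNum(tab$secondary_intensity, "secondary_intensity"), ids)
  else NULL

  if (!is.null(lib)) {
    libIds <- peptideIds(lib)
    missing <- setdiff(libIds, ids)
    extra <- setdiff(ids, libIds)
    if (length(missing) || length(extra))
      stop("intensity table does not match the library.",
           if (length(missing)) paste0(" Missing ids: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0(" Extra ids: ",
                                     paste(extra, collapse = ", ")))
    intensity <- intensity[libIds]
    if (!is.null(secondary)) secondary <- secondary[libIds]
  }
  list(intensity = intensity, secondary = secondary)
}

#' Write simulated binding profiles as tab-separated text
#'
#' One row per peptide with the raw Langmuir bound fraction and, when
#' supplied, the normalized signal.
#'
#' @param raw A [BindingProfile] at stage `"raw_fraction"`.
#' @param path Output path.
#' @param normalized Optional normalized [BindingProfile].
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(raw, path, normalized = NULL) {
  stopifnot(is(raw, "BindingProfile"))
  tab <- data.frame(peptide_id = names(profileValues(raw)),
                    raw_signal = unname(profileValues(raw)))
  if (!is.null(normalized))
    tab$normalized_signal <- unname(profileValues(normalized))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write AAWS tables
#'
#' AAWS are stored as 2-column tab-separated text (`amino_acid`, `weight`),
#' 20 rows in canonical alphabet order.
#'
#' @param w An [AAWSEstimate][AAWS-classes], [AssignedAAWS][AAWS-classes] or
#'   named numeric 20-vector.
#' @param path File path.
#' @return `writeAAWS()` returns `path` invisibly; `readAAWS()` returns a
#'   named numeric 20-vector.
#' @export
writeAAWS <- function(w, path) {
  wv <- if (is(w, "AAWSEstimate") || is(w, "AssignedAAWS")) aawsWeights(w)
        else .canonical20(w)
  tab <- data.frame(amino_acid = names(wv), weight = unname(wv))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAAWS
#' @export
readAAWS <- function(path) {
  tab <- read.delim(path, header = TRUE)
  if (!all(c("amino_acid", "weight") %in% colnames(tab)))
    stop("AAWS table must have columns amino_acid and weight")
  .canonical20(setNames(as.numeric(tab$weight),
                        as.character(tab$amino_acid)))
}

#' Read an amino-acid property-scale table
#'
#' Tab-separated text whose first column holds the 20 one-letter amino-acid
#' codes and whose remaining columns are numeric property or propensity
#' scales. The rows are reordered to the canonical alphabet.
#'
#' @param path File path.
#' @return A numeric matrix with 20 rows (canonical order), one column per
#'   scale.
#' @seealso [correlateWithScale()]
#' @export
readScaleTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE)
  aa <- toupper(as.character(tab[[1L]]))
  missing <- setdiff(.AA20, aa)
  if (length(missing))
    stop("scale table is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  M <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("scale columns must be numeric")
  rownames(M) <- aa
  M[match(.AA20, aa), , drop = FALSE]
}

#' Export an ensemble result as a long-format table
#'
#' Writes the [base::as.data.frame()] form of a [SweepResult-class], a
#' [DominanceResult-class], or a list of dominance results, as tab-separated
#' text.
#'
#' @param x The result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(x, path) {
  tab <- if (is.list(x) && !is.data.frame(x))
    do.call(rbind, lapply(x, as.data.frame))
  else as.data.frame(x)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
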