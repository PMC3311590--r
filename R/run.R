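#' RunConfig: a declarative description of one reproducible run
#'
#' A mode (`generate-library`, `simulate`, `fit`, `sweep`, `dominance`,
#' `pca`, `correlate-scale`) plus a named parameter list. All seeds are
#' explicit parameters - nothing depends on hidden global RNG state - so an
#' identical config yields byte-identical numeric outputs.
#'
#' @slot mode Run mode string.
#' @slot params Named list of parameters.
#' @seealso [readRunConfig()], [runFromConfig()]
#' @aliases RunConfig
#' @exportClass RunConfig
setClass("RunConfig", slots = c(mode = "character", params = "list"))

.RUN_MODES <- c("generate-library", "simulate", "fit", "sweep",
                "dominance", "pca", "correlate-scale")

setValidity("RunConfig", function(object) {
  if (length(object@mode) != 1L || !object@mode %in% .RUN_MODES)
    return(paste("mode must be one of:", paste(.RUN_MODES, collapse = ", ")))
  if (length(object@params) && is.null(names(object@params)))
    return("params must be named")
  TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig mode:", object@mode, "\n")
  for (k in names(object@params))
    cat(" ", k, "=", paste(object@params[[k]], collapse = ","), "\n")
})

#' Read a run configuration from a key-value text file
#'
#' The format is one `key = value` pair per line; `#` starts a comment.
#' A `mode` key is required. Values are parsed as numbers when possible,
#' `true`/`false` as logicals, comma-separated values as vectors, anything
#' else as strings.
#'
#' @param path Config file path.
#' @return A [RunConfig-class].
#' @examples
#' cfg <- tempfile()
#' writeLines(c("mode = generate-library", "n_pep = 10", "l = 14",
#'              "seed = 1", paste("out_library =", tempfile())), cfg)
#' readRunConfig(cfg)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty config file: ", path)
  hasEq <- grepl("=", lines, fixed = TRUE)
  if (any(!hasEq))
    stop("malformed config line(s): ",
         paste(lines[!hasEq], collapse = "; "))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  params <- lapply(vals, .parseConfigValue)
  names(params) <- keys
  if (is.null(params$mode)) stop("config must set a mode")
  mode <- as.character(params$mode)
  params$mode <- NULL
  new("RunConfig", mode = mode, params = params)
}

.parseConfigValue <- function(v) {
  parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
  if (length(parts) == 0L) return("")
  low <- tolower(parts)
  if (all(low %in% c("true", "false"))) return(low == "true")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  if (length(parts) == 1L) parts else parts
}

#' Execute a run configuration
#'
#' Dispatches on the config mode, writes the declared output files plus a
#' `.manifest.txt` recording every parameter, seed and the package version,
#' and logs progress to stderr. On failure, partially written outputs are
#' removed. Identical config (seeds included) produces byte-identical
#' outputs.
#'
#' Supported modes and their main parameters:
#' \describe{
#'   \item{`generate-library`}{`n_pep`, `l`, `seed`, optional `unique`,
#'     `out_library`.}
#'   \item{`simulate`}{`library` (path) or `n_pep` + `l` + `library_seed`;
#'     `h_seed`; `n_ab`, `mixture_seed`; optional `sigma`, `noise_seed`,
#'     `dominance_factor`, thermodynamic overrides `gas_constant`,
#'     `temperature`, `beta0`, `beta1`; `out_profile`.}
#'   \item{`fit`}{`library`, `intensities` (tab-separated
#'     `peptide_id`/`intensity`[/`secondary_intensity`] of raw intensities),
#'     optional `folds`, `fold_seed`, `n_components`; `out_aaws`, optional
#'     `out_cv`.}
#'   \item{`sweep`}{`library` or `n_pep` + `l` + `library_seed`; `h_seed`;
#'     `grid`, `reps`, optional `sigma`; `seed`; `out_table`, optional
#'     `out_pairwise`.}
#'   \item{`dominance`}{library/h as above; `reps`, optional `n_ab`,
#'     `sigma`; `seed`; `out_table`.}
#'   \item{`pca`}{`aaws_matrix` (tab-separated, first column sample id, 20
#'     amino-acid columns), optional `k`, `scale`; `out_scores`,
#'     `out_loadings`.}
#'   \item{`correlate-scale`}{`aaws` ([writeAAWS()] format), `scale_table`
#'     ([readScaleTable()] format), optional `method`; `out_table`.}
#' }
#'
#' @param config A [RunConfig-class], or the path to a config file.
#' @return Invisibly, a character vector of the files written.
#' @examples
#' cfg <- new("RunConfig", mode = "generate-library",
#'            params = list(n_pep = 10, l = 14, seed = 1,
#'                          out_library = tempfile(fileext = ".tsv")))
#' out <- runFromConfig(cfg)
#' @export
runFromConfig <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  p <- config@params
  written <- character(0)
  note <- function(...) message("[pepAAWS] ", ...)

  run <- function() {
    switch(config@mode,
      "generate-library" = {
        lib <- generateLibrary(.need(p, "n_pep"), .need(p, "l"),
                               seed = .need(p, "seed"),
                               unique = isTRUE(p[["unique"]]))
        out <- .need(p, "out_library")
        writeLibrary(lib, out)
        written <<- c(written, out)
        note("wrote library of ", length(lib), " peptides to ", out)
      },
      "simulate" = {
        lib <- .configLibrary(p)
        h <- sampleAssignedAAWS(seed = .need(p, "h_seed"))
        theta <- .configThermo(p)
        mix <- makeMixture(.need(p, "n_ab"), peptideLength(lib),
                           seed = .need(p, "mixture_seed"),
                           dominanceFactor = p[["dominance_factor"]] %||% 1)
        prof <- simulateSignal(lib, mix, h, theta)
        sigma <- p[["sigma"]] %||% 0
        if (sigma > 0)
          prof <- applyNoise(prof, sigma, seed = .need(p, "noise_seed"))
        norm <- normalizeSignal(prof)
        out <- .need(p, "out_profile")
        writeProfileTable(prof, out, normalized = norm)
        written <<- c(written, out)
        note("wrote simulated profile (", length(prof), " peptides) to ", out)
      },
      "fit" = {
        lib <- readLibrary(.need(p, "library"))
        tab <- readIntensityTable(.need(p, "intensities"), lib = lib)
        if (any(tab$intensity <= 0))
          stop("raw intensities must be positive for the log transform")
        if (!is.null(tab$secondary)) {
          corr <- secondaryCorrection(log(tab$intensity),
                                      log(tab$secondary))
          s <- corr$profile
        } else {
          s <- normalizeSignal(BindingProfile(values = log(tab$intensity),
                                              stage = "logged"))
        }
        X <- compositionMatrix(lib)
        nc <- p[["n_components"]]
        fit <- fitAAWS(s, X, nComponents = nc,
                       fittedOn = basename(.need(p, "intensities")))
        outA <- .need(p, "out_aaws")
        writeAAWS(fit, outA)
        written <<- c(written, outA)
        cv <- q2CrossValidation(s, X, folds = p[["folds"]] %||% 10,
                                seed = .need(p, "fold_seed"),
                                nComponents = nc)
        note("fit AAWS (", fit@nComponents, " components), Q2 = ",
             round(q2(cv), 4))
        if (!is.null(p[["out_cv"]])) {
          writeLines(c(paste0("q2 = ", format(q2(cv), digits = 15)),
                       paste0("folds = ", length(cv@perFoldPress)),
                       paste0("n_components = ",
                              paste(cv@nComponents, collapse = ","))),
                     p[["out_cv"]])
          written <<- c(written, p[["out_cv"]])
        }
      },
      "sweep" = {
        lib <- .configLibrary(p)
        h <- sampleAssignedAAWS(seed = .need(p, "h_seed"))
        sw <- diversitySweep(lib, h, nAbGrid = .need(p, "grid"),
                             reps = .need(p, "reps"),
                             sigma = p[["sigma"]] %||% 0,
                             theta = .configThermo(p),
                             seed = .need(p, "seed"))
        out <- .need(p, "out_table")
        reps <- length(sw@q2Samples[[1L]])
        tab <- data.frame(n_ab = rep(sw@nAbGrid, each = reps),
                          replicate = rep(seq_len(reps),
                                          length(sw@nAbGrid)),
                          q2 = unlist(sw@q2Samples),
                          h_recovery = unlist(sw@hRecoverySamples))
        write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, out)
        if (!is.null(p[["out_pairwise"]])) {
          ptab <- data.frame(
            n_ab = rep(sw@nAbGrid, lengths(sw@pairwiseRSamples)),
            pair = unlist(lapply(sw@pairwiseRSamples, seq_along)),
            pairwise_r = unlist(sw@pairwiseRSamples))
          write.table(ptab, p[["out_pairwise"]], sep = "\t", quote = FALSE,
                      row.names = FALSE)
          written <<- c(written, p[["out_pairwise"]])
        }
        note("wrote sweep table (", nrow(tab), " rows) to ", out)
      },
      "dominance" = {
        lib <- .configLibrary(p)
        h <- sampleAssignedAAWS(seed = .need(p, "h_seed"))
        dom <- dominanceExperiment(lib, h, reps = .need(p, "reps"),
                                   nAb = p[["n_ab"]] %||% 16000,
                                   sigma = p[["sigma"]] %||% 0.01,
                                   theta = .configThermo(p),
                                   seed = .need(p, "seed"))
        out <- .need(p, "out_table")
        writeResultTable(dom, out)
        written <<- c(written, out)
        note("wrote dominance table to ", out)
      },
      "pca" = {
        tab <- read.delim(.need(p, "aaws_matrix"), header = TRUE)
        M <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(M) <- as.character(tab[[1L]])
        res <- pcaAAWS(M[, .AA20, drop = FALSE], k = p[["k"]] %||% 2,
                       scale = isTRUE(p[["scale"]]))
        outS <- .need(p, "out_scores")
        outL <- .need(p, "out_loadings")
        write.table(data.frame(sample = rownames(M), res@scores),
                    outS, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(amino_acid = .AA20, res@loadings),
                    outL, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, outS, outL)
        note("PCA variance explained: ",
             paste(signif(res@varianceExplained, 3), collapse = ", "))
      },
      "correlate-scale" = {
        w <- readAAWS(.need(p, "aaws"))
        scales <- readScaleTable(.need(p, "scale_table"))
        r <- correlateWithScale(w, scales,
                                method = p[["method"]] %||% "pearson")
        out <- .need(p, "out_table")
        write.table(data.frame(scale = names(r), r = unname(r)),
                    out, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, out)
        note("wrote ", length(r), " scale correlations to ", out)
      }
    )
  }

  tryCatch(run(), error = function(e) {
    existing <- written[file.exists(written)]
    if (length(existing)) unlink(existing)
    stop("run failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- paste0(written[1L], ".manifest.txt")
  writeLines(c(paste0("package = pepAAWS ",
                      as.character(packageVersion("pepAAWS"))),
               paste0("mode = ", config@mode),
               vapply(names(p), function(k)
                 paste0(k, " = ", paste(p[[k]], collapse = ",")),
                 character(1L)),
               paste0("outputs = ", paste(written, collapse = ","))),
             manifest)
  invisible(c(written, manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.need <- function(p, key) {
  if (is.null(p[[key]]))
    stop("config parameter '", key, "' is required for this mode")
  p[[key]]
}

.configLibrary <- function(p) {
  if (!is.null(p[["library"]])) {
    if (!file.exists(p[["library"]]))
      stop("library file not found: ", p[["library"]])
    readLibrary(p[["library"]])
  } else {
    generateLibrary(.need(p, "n_pep"), .need(p, "l"),
                    seed = .need(p, "library_seed"))
  }
}

.configThermo <- function(p) {
  thermoParams(
    gasConstant = p[["gas_constant"]] %||% 8.314472,
    temperature = p[["temperature"]] %||% (273.15 + 25),
    beta0 = p[["beta0"]] %||% 0,
    beta1 = p[["beta1"]] %||%
      ((p[["gas_constant"]] %||% 8.314472) * (p[["temperature"]] %||% (273.15 + 25))))
}
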