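#' Load the default 131-measure catalog
#'
#' Returns the curated catalog of 131 measures from twelve standard
#' neuropsychological instruments, with cognitive-domain assignments,
#' raw-score bounds, polarity, and the expert annotation: 32 measures are
#' retained for classification and the remaining 99 carry an exclusion code
#' (1 = redundancy, 2 = overlap with the CDR gold standard, 3 = poor
#' relevance to Alzheimer's disease). The catalog ships as a CSV inside the
#' package so alternative catalogs can be supplied through [readCatalog()].
#'
#' @return A \linkS4class{MeasureCatalog} with 131 entries.
#' @examples
#' cat131 <- defaultCatalog()
#' length(measureNames(cat131))          # 131
#' sum(expertRetained(cat131))           # 32
#' @export
defaultCatalog <- function() {
  path <- system.file("extdata", "measure_catalog.csv", package = "npOptim",
                      mustWork = TRUE)
  readCatalog(path)
}

#' Read and write measure catalogs
#'
#' The catalog file format is UTF-8 CSV with header columns `name`, `test`,
#' `domain`, `score_min`, `score_max`, `polarity`, `expert_retained`,
#' `exclusion_code`, `exclusion_note`. `exclusion_code` is empty for
#' expert-retained measures and 1, 2 or 3 otherwise.
#'
#' @param path file to read from or write to.
#' @param catalog a \linkS4class{MeasureCatalog}.
#' @return `readCatalog` returns a \linkS4class{MeasureCatalog};
#'   `writeCatalog` invisibly returns `path`.
#' @export
readCatalog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$expert_retained <- as.logical(df$expert_retained)
  df$exclusion_code <- suppressWarnings(as.integer(df$exclusion_code))
  if (!"exclusion_note" %in% colnames(df)) df$exclusion_note <- NA_character_
  df$exclusion_note[is.na(df$exclusion_note)] <- ""
  rownames(df) <- NULL
  new("MeasureCatalog", measures = df[, .CATALOG_COLUMNS])
}

#' @rdname readCatalog
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "MeasureCatalog"))
  write.csv(catalog@measures, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Catalog accessors
#'
#' `measureNames` returns the ordered measure names; `expertRetained` the
#' logical retained flag (named by measure); `catalogTable` the underlying
#' data.frame; `lookupMeasure` a single measure's definition as a one-row
#' data.frame.
#'
#' @param catalog a \linkS4class{MeasureCatalog}.
#' @param name a measure name present in the catalog.
#' @export
measureNames <- function(catalog) catalog@measures$name

#' @rdname measureNames
#' @export
expertRetained <- function(catalog)
  setNames(catalog@measures$expert_retained, catalog@measures$name)

#' @rdname measureNames
#' @export
catalogTable <- function(catalog) catalog@measures

#' @rdname measureNames
#' @export
lookupMeasure <- function(catalog, name) {
  i <- match(name, catalog@measures$name)
  if (is.na(i)) stop("unknown measure: ", name)
  catalog@measures[i, , drop = FALSE]
}

#' Select a sub-catalog
#'
#' Filters the catalog by a predicate expression over its columns (`name`,
#' `test`, `domain`, `score_min`, `score_max`, `polarity`,
#' `expert_retained`, `exclusion_code`, `exclusion_note`), preserving order.
#' An empty selection is allowed.
#'
#' @param catalog a \linkS4class{MeasureCatalog}.
#' @param predicate an expression evaluated in the catalog's columns, e.g.
#'   `expert_retained` or `test == "MMSE"`.
#' @return A \linkS4class{MeasureCatalog} containing the matching entries.
#' @examples
#' nrow(catalogTable(selectMeasures(defaultCatalog(), expert_retained)))  # 32
#' @export
selectMeasures <- function(catalog, predicate) {
  stopifnot(is(catalog, "MeasureCatalog"))
  df <- catalog@measures
  keep <- tryCatch(
    eval(substitute(predicate), envir = df, enclos = parent.frame()),
    error = function(e) stop("invalid selection predicate: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.logical(keep) || length(keep) != nrow(df))
    stop("selection predicate must yield one logical per measure")
  keep[is.na(keep)] <- FALSE
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("MeasureCatalog", measures = out)
}

setMethod("show", "MeasureCatalog", function(object) {
  df <- object@measures
  cat(sprintf("MeasureCatalog with %d measures (%d expert-retained)\n",
              nrow(df), sum(df$expert_retained)))
  cat("  instruments:", paste(unique(df$test), collapse = ", "), "\n")
})
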