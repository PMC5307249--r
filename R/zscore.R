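.asScoreMatrix <- function(x) {
  if (is(x, "NPCohort")) scoreMatrix(x)
  else if (is.matrix(x)) x
  else stop("expected an NPCohort or a subjects-by-measures matrix")
}

#' Fit a z-score normalization model
#'
#' Computes per-measure mean m and sample (n - 1) standard deviation s over
#' the given subjects, for later standardization z = (score - m) / s.
#' Fitting on training subjects only and applying to held-out subjects keeps
#' the normalization free of information leakage.
#'
#' @param x an \linkS4class{NPCohort} or a subjects-by-measures matrix.
#' @param measures measure names to fit (default: all columns).
#' @param subset optional row (subject) indices to fit on.
#' @return A \linkS4class{ZScoreModel}.
#' @examples
#' m <- fitZScore(matrix(c(10, 20, 30), ncol = 1,
#'                       dimnames = list(NULL, "A")))
#' c(m@center, m@scale)   # 20, 10
#' @export
fitZScore <- function(x, measures = NULL, subset = NULL) {
  X <- .asScoreMatrix(x)
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  if (is.null(measures)) measures <- colnames(X)
  missing <- setdiff(measures, colnames(X))
  if (length(missing))
    stop("measure(s) absent: ", paste(missing, collapse = ", "))
  if (nrow(X) < 2) stop("need at least 2 subjects to fit a z-score model")
  X <- X[, measures, drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop("cannot standardize constant measure(s): ",
         paste(measures[zero], collapse = ", "))
  new("ZScoreModel", measures = measures, center = unname(ctr),
      scale = unname(scl))
}

#' Apply a z-score model
#'
#' Standardizes scores elementwise as (score - m) / s using the model's own
#' m and s, not those of the target subjects; applied to held-out subjects
#' the column means are therefore unconstrained.
#'
#' @param model a \linkS4class{ZScoreModel}.
#' @param x an \linkS4class{NPCohort} or subjects-by-measures matrix whose
#'   columns include all model measures.
#' @return A subjects-by-measures matrix of z-scores (model measures only,
#'   in model order).
#' @export
applyZScore <- function(model, x) {
  X <- .asScoreMatrix(x)
  missing <- setdiff(model@measures, colnames(X))
  if (length(missing))
    stop("measure(s) in model missing from data: ",
         paste(missing, collapse = ", "))
  X <- X[, model@measures, drop = FALSE]
  scale(X, center = model@center, scale = model@scale)[, , drop = FALSE]
}

#' Serialize a z-score model to JSON
#'
#' @param model a \linkS4class{ZScoreModel}.
#' @param path JSON file path; the format is `measure -> {m, s}` plus an
#'   `sd_convention` field recording the n - 1 choice.
#' @export
writeZScoreModel <- function(model, path) {
  payload <- list(sd_convention = "sample (n-1)",
                  measures = setNames(
                    lapply(seq_along(model@measures), function(i)
                      list(m = model@center[i], s = model@scale[i])),
                    model@measures))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeZScoreModel
#' @export
readZScoreModel <- function(path) {
  payload <- jsonlite::read_json(path)
  ms <- payload$measures
  new("ZScoreModel", measures = names(ms),
      center = unname(vapply(ms, function(e) e$m, 0)),
      scale = unname(vapply(ms, function(e) e$s, 0)))
}

setMethod("show", "ZScoreModel", function(object) {
  cat(sprintf("ZScoreModel over %d measures (sample-SD convention)\n",
              length(object@measures)))
})
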