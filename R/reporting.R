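# Reporting is deterministic formatting of already-computed results; no
# model is ever refitted here.

.KERNEL_ORDER <- c("linear", "quadratic", "rbf", "mlp")
.KERNEL_LABELS <- c(linear = "Linear", quadratic = "Quadratic",
                    rbf = "Gaussian RBF", mlp = "Multilayer Perceptron")

.fmtMeanSD <- function(m, s) sprintf("%.2f ± %.2f", m, s)

#' Render a per-kernel performance table
#'
#' One row per kernel (fixed order: linear, quadratic, Gaussian RBF,
#' multilayer perceptron), columns accuracy, sensitivity, specificity,
#' geometric mean and dominance as "mean ± sd" at two decimals. All
#' results must come from the same comparison task.
#'
#' @param results a list of \linkS4class{NestedCVResult} objects (one per
#'   kernel).
#' @return data.frame of formatted strings with a `kernel` column.
#' @export
renderPerformanceTable <- function(results) {
  if (!length(results)) stop("need at least one kernel result")
  if (is(results, "NestedCVResult")) results <- list(results)
  tasks <- unique(vapply(results, function(r) r@task, ""))
  if (length(tasks) != 1)
    stop("mixed tasks in one table: ", paste(tasks, collapse = ", "))
  kinds <- vapply(results, function(r) r@kernel@kind, "")
  results <- results[order(match(kinds, .KERNEL_ORDER))]
  rows <- lapply(results, function(r) {
    s <- cvSummary(r)
    g <- function(metric) {
      i <- match(metric, s$metric)
      .fmtMeanSD(s$mean[i], s$sd[i])
    }
    data.frame(kernel = .KERNEL_LABELS[[r@kernel@kind]],
               accuracy = g("accuracy"), sensitivity = g("sensitivity"),
               specificity = g("specificity"),
               geometric_mean = g("geometric_mean"),
               dominance = g("dominance"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a best-predictor frequency table
#'
#' Descending top-N slice with formatted percentages: two significant
#' habits of the field's tables are kept -- whole percents at or above 1%
#' and one decimal below 1%.
#'
#' @param freqs data.frame from [bestPredictorFrequencies()] (columns
#'   measure, count, percent).
#' @param top rows to keep (all rows if fewer are available).
#' @return data.frame with columns rank, measure, frequency.
#' @export
renderFrequencyTable <- function(freqs, top = 10) {
  out <- utils::head(freqs[order(-freqs$percent), , drop = FALSE], top)
  if (!nrow(out))
    return(data.frame(rank = integer(), measure = character(),
                      frequency = character()))
  data.frame(rank = seq_len(nrow(out)), measure = out$measure,
             frequency = ifelse(out$percent < 1,
                                sprintf("%.1f%%", out$percent),
                                sprintf("%.0f%%", out$percent)),
             row.names = NULL)
}

#' Bar plot of a feature ranking
#'
#' Plots ranked scores (FDR values, single-feature accuracies or
#' best-predictor percentages) as a bar chart with an optional retention
#' cut-off marker.
#'
#' @param ranking data.frame with columns `measure` and a numeric score
#'   column (`score` or `percent`).
#' @param cutoff optional number of retained features; a vertical line is
#'   drawn after that many bars.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted values.
#' @export
plotRanking <- function(ranking, cutoff = NULL, ylab = "score", ...) {
  scores <- if ("score" %in% colnames(ranking)) ranking$score
            else ranking$percent
  mid <- graphics::barplot(scores, names.arg = ranking$measure, las = 2,
                           cex.names = 0.6, ylab = ylab, ...)
  if (!is.null(cutoff) && cutoff < length(scores))
    graphics::abline(v = (mid[cutoff] + mid[cutoff + 1]) / 2, lty = 2,
                     col = "red3")
  invisible(setNames(scores, ranking$measure))
}

#' Export a nested-CV run to disk
#'
#' Writes the shapes a full analysis reports: `metrics.tsv` (aggregate
#' metrics), `rounds.tsv` (per-round inner/outer accuracy),
#' `frequencies.tsv` (best-predictor frequencies) and `run.json` (the run
#' manifest: configuration snapshot, seed trail, package version and md5
#' digests of the emitted files -- enough to replay the run).
#'
#' @param result a \linkS4class{NestedCVResult}.
#' @param dir output directory (created if absent).
#' @param top frequency-table depth.
#' @return Invisibly, the manifest as a list.
#' @export
exportRun <- function(result, dir, top = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("metrics.tsv", "rounds.tsv", "frequencies.tsv"))
  utils::write.table(cvSummary(result), paths[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(innerOuterByRound(result), paths[2], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bestPredictorFrequencies(result, top = top), paths[3],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("npOptim")),
    task = result@task, strategy = result@strategy,
    kernel = list(kind = result@kernel@kind, sigma = result@kernel@sigma,
                  mlp_scale = result@kernel@mlpScale,
                  cost = result@kernel@cost),
    rounds = result@rounds, iterations = result@iterations,
    master_seed = result@seed,
    iteration_seeds = vapply(result@folds, function(f) f$seed, 0),
    solver_failures = nrow(result@failures),
    files = setNames(as.list(unname(tools::md5sum(paths))),
                     basename(paths)))
  jsonlite::write_json(manifest, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
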