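#' @import methods
#' @importFrom stats sd rnorm
#' @importFrom utils combn read.csv write.csv
#' @importFrom stats setNames
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom jsonlite write_json read_json
NULL

.DOMAINS <- c("global_cognitive_status", "language", "executive_functioning",
              "memory_learning", "perceptual_motor", "complex_attention",
              "working_memory", "visuoconstructional", "orientation",
              "functional_abilities", "depression")

.TESTS <- c("MMSE", "Clock", "LM", "AVLT", "DS", "CategoryFluency", "TMT",
            "BNT", "ANART", "ADAS-Cog", "GDS", "FAQ")

.POLARITIES <- c("higher_worse", "higher_better")

.CDR_LEVELS <- c(0, 0.5, 1)

.CATALOG_COLUMNS <- c("name", "test", "domain", "score_min", "score_max",
                      "polarity", "expert_retained", "exclusion_code",
                      "exclusion_note")

#' Catalog of neuropsychological measures
#'
#' An ordered collection of measure definitions: one row per measure with the
#' source instrument, cognitive domain, inclusive raw-score bounds, polarity
#' (whether a higher raw score indicates worse performance), and the expert
#' annotation (retained for classification, or an exclusion code 1 =
#' redundancy with another measure, 2 = overlap with the CDR gold standard,
#' 3 = poor relevance to Alzheimer's disease).
#'
#' @slot measures data.frame with one row per measure; see
#'   [readCatalog()] for the column contract.
#' @seealso [defaultCatalog()], [selectMeasures()]
#' @export
setClass("MeasureCatalog", representation(measures = "data.frame"))

setValidity("MeasureCatalog", function(object) {
  df <- object@measures
  msg <- character()
  missing_cols <- setdiff(.CATALOG_COLUMNS, colnames(df))
  if (length(missing_cols))
    return(paste("missing catalog columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$name))
    msg <- c(msg, "measure names must be unique")
  if (!all(df$score_min <= df$score_max))
    msg <- c(msg, "score_min must not exceed score_max")
  if (!all(df$polarity %in% .POLARITIES))
    msg <- c(msg, "polarity must be 'higher_worse' or 'higher_better'")
  if (!all(df$domain %in% .DOMAINS))
    msg <- c(msg, paste("unknown domain:",
                        paste(setdiff(df$domain, .DOMAINS), collapse = ", ")))
  code <- df$exclusion_code
  if (!all(is.na(code) | code %in% 1:3))
    msg <- c(msg, "exclusion_code must be 1, 2, 3 or absent")
  if (!all(xor(df$expert_retained, !is.na(code))))
    msg <- c(msg, "each measure must be either expert-retained or carry an exclusion code")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Cohort of subjects with neuropsychological scores
#'
#' Extends \linkS4class{SummarizedExperiment}: the `"scores"` assay holds the
#' measures-by-subjects matrix of raw instrument scores, `rowData` carries the
#' measure catalog columns, and `colData` holds `subject_id` and the `cdr`
#' label (0, 0.5 or 1). Generated cohorts may additionally carry a `"latent"`
#' assay with the pre-discretization standardized scores.
#'
#' @seealso [generateCohort()], [readCohort()]
#' @export
setClass("NPCohort", contains = "SummarizedExperiment")

setValidity("NPCohort", function(object) {
  msg <- character()
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    return("cohort must carry a 'scores' assay")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "cdr") %in% colnames(cd)))
    return("colData must contain 'subject_id' and 'cdr'")
  if (!all(cd$cdr %in% .CDR_LEVELS))
    msg <- c(msg, "cdr labels must be 0, 0.5 or 1")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("score_min", "score_max") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry score_min and score_max")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Configuration for the synthetic cohort generator
#'
#' @slot groupSizes integer vector named "0", "0.5", "1": subjects per CDR
#'   group (defaults 126, 143, 55).
#' @slot planted named list: measure name -> numeric length-3 vector of
#'   standardized mean shifts (impairment direction) for CDR 0, 0.5 and 1.
#' @slot rho equicorrelation of latent scores within each instrument block.
#' @slot noiseSD standard deviation of the latent scores, in standardized
#'   units (planted shifts are expressed relative to it).
#' @slot seed integer seed fully determining the generated cohort.
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
         representation(groupSizes = "numeric", planted = "list",
                        rho = "numeric", noiseSD = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!identical(names(object@groupSizes), c("0", "0.5", "1")))
    msg <- c(msg, "groupSizes must be named '0', '0.5', '1'")
  if (any(object@groupSizes < 10))
    msg <- c(msg, "each CDR group needs at least 10 subjects to permit 10-fold splitting")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@noiseSD <= 0)
    msg <- c(msg, "noiseSD must be positive")
  if (length(object@planted) &&
      (is.null(names(object@planted)) ||
       !all(vapply(object@planted, length, 1L) == 3L)))
    msg <- c(msg, "planted must be a named list of length-3 shift vectors")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-measure standardization model
#'
#' Centers and scales raw scores as z = (score - m) / s, with m and s the
#' mean and sample (n - 1) standard deviation of the subjects the model was
#' fitted on. Fitting on training subjects and applying to held-out subjects
#' keeps the normalization leakage-free.
#'
#' @slot measures measure names in fitting order.
#' @slot center per-measure mean m.
#' @slot scale per-measure standard deviation s (always > 0).
#' @seealso [fitZScore()], [applyZScore()]
#' @export
setClass("ZScoreModel",
         representation(measures = "character", center = "numeric",
                        scale = "numeric"))

setValidity("ZScoreModel", function(object) {
  if (length(object@measures) != length(object@center) ||
      length(object@measures) != length(object@scale))
    return("measures, center and scale must have equal length")
  if (any(object@scale <= 0))
    return("all scale values must be positive")
  TRUE
})

#' SVM kernel configuration
#'
#' One of four kernels: linear x.y, quadratic (1 + x.y)^2, Gaussian RBF
#' exp(-||x - y||^2 / (2 sigma^2)) with default sigma = 1, or the sigmoid
#' multilayer-perceptron kernel tanh(p1 x.y + p2) with default scale
#' (1, -1). The soft-margin cost defaults to 1.
#'
#' @slot kind "linear", "quadratic", "rbf" or "mlp".
#' @slot sigma RBF bandwidth (used only for kind "rbf").
#' @slot mlpScale numeric length 2, the (p1, p2) of the sigmoid kernel.
#' @slot cost soft-margin cost C.
#' @seealso [kernelConfig()], [kernelEval()]
#' @export
setClass("KernelConfig",
         representation(kind = "character", sigma = "numeric",
                        mlpScale = "numeric", cost = "numeric"))

setValidity("KernelConfig", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "quadratic", "rbf", "mlp"))
    msg <- c(msg, "kind must be linear, quadratic, rbf or mlp")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(object@mlpScale) != 2) msg <- c(msg, "mlpScale must have length 2")
  if (object@cost <= 0) msg <- c(msg, "cost must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Trained binary SVM
#'
#' Stores the dual solution so the decision function
#' y(x) = sum_n w_n t_n k(x, x_n) + b can be evaluated directly: `weights`
#' holds the signed products w_n t_n, `supports` the support samples x_n,
#' and `bias` the threshold b. Predictions are the sign of y(x); an exact
#' zero is assigned to the positive class.
#'
#' @slot supports support-vector matrix (one row per support sample).
#' @slot weights signed dual weights w_n t_n.
#' @slot bias threshold b.
#' @slot kernel the \linkS4class{KernelConfig} used for training.
#' @slot features column names the model expects, in training order.
#' @seealso [trainSVM()], [decisionValues()]
#' @export
setClass("TrainedSVM",
         representation(supports = "matrix", weights = "numeric",
                        bias = "numeric", kernel = "KernelConfig",
                        features = "character"))

setValidity("TrainedSVM", function(object) {
  if (nrow(object@supports) != length(object@weights))
    return("one weight per support sample required")
  if (ncol(object@supports) != length(object@features))
    return("supports must have one column per feature")
  TRUE
})

#' Result of a feature-reduction strategy
#'
#' @slot strategy "fdr_filter" or "expert_accuracy".
#' @slot ranking data.frame with columns `measure` and `score`, in
#'   descending score order (ties broken by catalog order).
#' @slot retained measure names surviving the strategy's cut-off rule.
#' @slot provenance list describing the comparison task and data slice.
#' @seealso [reduceByFDR()], [rankBySingleFeatureAccuracy()]
#' @export
setClass("ReductionResult",
         representation(strategy = "character", ranking = "data.frame",
                        retained = "character", provenance = "list"))

setValidity("ReductionResult", function(object) {
  if (!object@strategy %in% c("fdr_filter", "expert_accuracy"))
    return("strategy must be fdr_filter or expert_accuracy")
  if (!all(object@retained %in% object@ranking$measure))
    return("retained measures must appear in the ranking")
  TRUE
})

#' Result of a nested cross-validation run
#'
#' Holds every per-(round, iteration) record of a class-balanced nested
#' 10-fold cross-validation with exhaustive feature-subset optimization:
#' the optimal subset selected in the inner loop, its inner-loop accuracy,
#' and the outer-loop confusion-derived metrics, plus the fold plans and
#' seed trail needed to replay any part of the run.
#'
#' @slot task comparison label, e.g. "1v0" (positive class first).
#' @slot strategy reduction strategy used per round.
#' @slot kernel the \linkS4class{KernelConfig} used throughout.
#' @slot rounds,iterations dimensions of the resampling grid.
#' @slot records data.frame with one row per (round, iteration): the
#'   inner-loop accuracy of the selected subset and the outer-loop
#'   accuracy, sensitivity, specificity, geometric mean and dominance.
#' @slot subsets list (length rounds x iterations) of optimal feature sets.
#' @slot reduced list of the per-round reduced candidate sets.
#' @slot folds per-iteration fold plans (balanced subject indices, fold
#'   assignment, iteration seed).
#' @slot featureOrder catalog order of candidate features (tie-break key).
#' @slot failures data.frame logging solver failures (possible with the
#'   indefinite mlp kernel); failed rounds carry NA metrics.
#' @slot seed master seed of the run.
#' @seealso [runNestedCV()], [cvSummary()], [bestPredictorFrequencies()]
#' @export
setClass("NestedCVResult",
         representation(task = "character", strategy = "character",
                        kernel = "KernelConfig", rounds = "integer",
                        iterations = "integer", records = "data.frame",
                        subsets = "list", reduced = "list", folds = "list",
                        featureOrder = "character", failures = "data.frame",
                        seed = "integer"))

setValidity("NestedCVResult", function(object) {
  n <- object@rounds * object@iterations
  if (length(object@subsets) != n)
    return(sprintf("expected %d optimal subsets, found %d", n,
                   length(object@subsets)))
  if (nrow(object@records) != n)
    return("records must have one row per (round, iteration)")
  TRUE
})
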