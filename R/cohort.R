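#' Default planted group effects
#'
#' Standardized mean shifts (in units of the latent standard deviation, on
#' the impairment axis) for a set of measures known to track dementia
#' severity: episodic-memory scores (logical memory, ADAS word recall),
#' global composites (ADAS totals, MMSE total) and functional abilities
#' (FAQ). Shifts are graded across CDR 0 / 0.5 / 1, with the mild group
#' roughly halfway to the severe group, so the 0.5-vs-0 contrast is harder
#' than 1-vs-0 and 1-vs-0.5 is hardest -- the ordering clinical cohorts
#' show.
#'
#' @return Named list: measure -> numeric shifts for CDR 0, 0.5, 1.
#' @export
defaultPlantedEffects <- function() {
  list(
    LDELTOTAL = c(0, 1.2, 2.0),
    LIMMTOTAL = c(0, 1.0, 1.8),
    TOTALMOD  = c(0, 0.9, 1.9),
    TOTAL11   = c(0, 0.8, 1.7),
    Q1        = c(0, 0.7, 1.4),
    Q4        = c(0, 1.0, 1.8),
    Q8        = c(0, 0.6, 1.3),
    MMSCORE   = c(0, 0.6, 1.5),
    CATVEGESC = c(0, 0.5, 1.0),
    FAQTOTAL  = c(0, 0.7, 1.7)
  )
}

#' Build a synthetic-cohort configuration
#'
#' @param groupSizes subjects per CDR group, named "0", "0.5", "1"
#'   (defaults 126, 143, 55; each at least 10 so 10-fold splitting works).
#' @param planted named list of per-group standardized mean shifts; see
#'   [defaultPlantedEffects()].
#' @param rho within-instrument equicorrelation of the latent scores.
#' @param noiseSD latent standard deviation in standardized units.
#' @param seed integer seed; the generated cohort is fully determined by it.
#' @return A \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(groupSizes = c("0" = 126, "0.5" = 143, "1" = 55),
                         planted = defaultPlantedEffects(),
                         rho = 0.3, noiseSD = 1, seed = 1L) {
  gs <- groupSizes
  names(gs) <- names(groupSizes)
  new("CohortConfig", groupSizes = gs, planted = planted,
      rho = rho, noiseSD = noiseSD, seed = as.integer(seed))
}

#' Read or write a cohort configuration as YAML
#'
#' @param path YAML file with fields `group_sizes`, `planted`, `rho`,
#'   `noise_sd`, `seed`.
#' @param config a \linkS4class{CohortConfig}.
#' @export
readCohortConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gs <- unlist(y$group_sizes)
  cohortConfig(groupSizes = setNames(as.numeric(gs), names(gs)),
               planted = lapply(y$planted, as.numeric),
               rho = y$rho %||% 0.3, noiseSD = y$noise_sd %||% 1,
               seed = y$seed %||% 1L)
}

#' @rdname readCohortConfig
#' @export
writeCohortConfig <- function(config, path) {
  yaml::write_yaml(list(
    group_sizes = as.list(config@groupSizes),
    planted = config@planted, rho = config@rho,
    noise_sd = config@noiseSD, seed = config@seed), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Latent model: per CDR group, each subject's scores within an instrument
# block are equicorrelated Gaussians,
#   latent = noiseSD * (sqrt(rho) * common + sqrt(1 - rho) * unique + shift),
# so planted shifts are means in units of the latent SD on the impairment
# axis. Polarity only enters when mapping to the raw instrument scale.
.generateLatent <- function(config, catalog) {
  df <- catalogTable(catalog)
  unknown <- setdiff(names(config@planted), df$name)
  if (length(unknown))
    stop("planted measure(s) not in catalog: ", paste(unknown, collapse = ", "))
  p <- nrow(df)
  sizes <- config@groupSizes
  n <- sum(sizes)
  latent <- matrix(0, n, p, dimnames = list(NULL, df$name))
  labels <- rep(as.numeric(names(sizes)), times = sizes)
  row0 <- 0L
  for (g in seq_along(sizes)) {
    ng <- sizes[[g]]
    shift <- setNames(numeric(p), df$name)
    for (m in names(config@planted))
      shift[m] <- config@planted[[m]][g]
    block <- matrix(0, ng, p)
    for (tst in unique(df$test)) {
      idx <- which(df$test == tst)
      common <- rnorm(ng)
      eps <- matrix(rnorm(ng * length(idx)), ng, length(idx))
      block[, idx] <- sqrt(config@rho) * common +
        sqrt(1 - config@rho) * eps
    }
    latent[row0 + seq_len(ng), ] <-
      config@noiseSD * sweep(block, 2, shift, "+")
    row0 <- row0 + ng
  }
  list(latent = latent, labels = labels)
}

# Raw-scale mapping: the latent impairment score is flipped by polarity,
# scaled so +/- 3 SD spans the instrument range, clipped and rounded to
# integers. Binary (0/1-width) items threshold the latent at zero.
.latentToRaw <- function(latent, catalog) {
  df <- catalogTable(catalog)
  raw <- latent
  for (j in seq_len(ncol(latent))) {
    lo <- df$score_min[j]; hi <- df$score_max[j]
    dir <- if (df$polarity[j] == "higher_worse") 1 else -1
    z <- dir * latent[, j]
    if (hi - lo == 1) {
      raw[, j] <- lo + as.integer(z > 0)
    } else {
      mid <- (lo + hi) / 2
      raw[, j] <- pmin(hi, pmax(lo, round(mid + z * (hi - lo) / 6)))
    }
  }
  raw
}

#' Generate a synthetic cohort
#'
#' Draws a subjects-by-measures table of integer scores emulating a clinical
#' dementia cohort: three CDR groups of configurable size, within-instrument
#' correlation blocks, and CDR-graded mean shifts on a configurable set of
#' planted discriminative measures. Latent Gaussian scores are mapped to
#' each measure's raw range by an affine transform honoring polarity, then
#' clipped and rounded; 0/1 items threshold the latent at zero. The output
#' is fully determined by the configuration seed.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param catalog a \linkS4class{MeasureCatalog} (default: the shipped
#'   131-measure catalog).
#' @param keepLatent if TRUE, the pre-discretization latent scores are kept
#'   as a second assay `"latent"`.
#' @return An \linkS4class{NPCohort}.
#' @examples
#' co <- generateCohort(cohortConfig(seed = 7))
#' table(cdrLabels(co))   # 126 / 143 / 55
#' @export
generateCohort <- function(config, catalog = defaultCatalog(),
                           keepLatent = FALSE) {
  stopifnot(is(config, "CohortConfig"), is(catalog, "MeasureCatalog"))
  validObject(config)
  set.seed(config@seed)
  lat <- .generateLatent(config, catalog)
  raw <- .latentToRaw(lat$latent, catalog)
  n <- nrow(raw)
  cd <- S4Vectors::DataFrame(
    subject_id = sprintf("S%04d", seq_len(n)),
    cdr = lat$labels)
  assays <- list(scores = t(raw))
  if (keepLatent) assays$latent <- t(lat$latent)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(catalogTable(catalog),
                                   row.names = measureNames(catalog)),
    colData = cd)
  colnames(se) <- cd$subject_id
  new("NPCohort", se)
}

#' Cohort accessors
#'
#' `scoreMatrix` returns the subjects-by-measures raw score matrix (the
#' transposed `"scores"` assay); `cdrLabels` the numeric CDR label per
#' subject; `cohortCatalog` the measure annotation as a data.frame.
#'
#' @param cohort an \linkS4class{NPCohort}.
#' @export
scoreMatrix <- function(cohort)
  t(SummarizedExperiment::assay(cohort, "scores"))

#' @rdname scoreMatrix
#' @export
cdrLabels <- function(cohort)
  SummarizedExperiment::colData(cohort)$cdr

#' @rdname scoreMatrix
#' @export
cohortCatalog <- function(cohort)
  as.data.frame(SummarizedExperiment::rowData(cohort))

setMethod("show", "NPCohort", function(object) {
  cat(sprintf("NPCohort: %d subjects x %d measures\n",
              ncol(object), nrow(object)))
  print(table(CDR = cdrLabels(object)))
})

#' Read and write cohort score tables
#'
#' The cohort file format is CSV with header `subject_id,cdr` followed by
#' one column per catalog measure. Reading validates every cell against the
#' catalog: unknown columns, labels outside {0, 0.5, 1}, missing cells and
#' out-of-range scores are rejected with the offending row and column named.
#'
#' @param cohort an \linkS4class{NPCohort}.
#' @param path CSV file path.
#' @param catalog the \linkS4class{MeasureCatalog} to validate against.
#' @param dropIncomplete if TRUE, rows with missing cells are dropped (with
#'   a warning) instead of rejected.
#' @return `readCohort` returns an \linkS4class{NPCohort}; `writeCohort`
#'   invisibly returns `path`.
#' @export
writeCohort <- function(cohort, path) {
  df <- data.frame(subject_id = colnames(cohort),
                   cdr = cdrLabels(cohort),
                   scoreMatrix(cohort), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, catalog = defaultCatalog(),
                       dropIncomplete = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "cdr") %in% colnames(df)))
    stop("cohort file must start with 'subject_id' and 'cdr' columns")
  meas <- setdiff(colnames(df), c("subject_id", "cdr"))
  unknown <- setdiff(meas, measureNames(catalog))
  if (length(unknown))
    stop("unknown measure column(s): ", paste(unknown, collapse = ", "))
  bad_lab <- which(!df$cdr %in% .CDR_LEVELS)
  if (length(bad_lab))
    stop(sprintf("row %d: cdr label %s outside {0, 0.5, 1}",
                 bad_lab[1], df$cdr[bad_lab[1]]))
  X <- as.matrix(df[, meas, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- NULL
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)[1, ]
    if (dropIncomplete) {
      keep <- !apply(is.na(X), 1, any)
      warning(sprintf("dropping %d incomplete row(s)", sum(!keep)))
      df <- df[keep, , drop = FALSE]
      X <- X[keep, , drop = FALSE]
    } else {
      stop(sprintf("row %d, column %s: missing score", miss[1],
                   meas[miss[2]]))
    }
  }
  ct <- catalogTable(catalog)
  for (m in meas) {
    i <- match(m, ct$name)
    out <- which(X[, m] < ct$score_min[i] | X[, m] > ct$score_max[i])
    if (length(out))
      stop(sprintf("row %d, column %s: score %s outside range %d-%d",
                   out[1], m, X[out[1], m], ct$score_min[i], ct$score_max[i]))
  }
  sub <- selectMeasures(catalog, name %in% meas)
  # preserve catalog order for measures present in the file
  X <- X[, measureNames(sub), drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = t(X)),
    rowData = S4Vectors::DataFrame(catalogTable(sub),
                                   row.names = measureNames(sub)),
    colData = S4Vectors::DataFrame(subject_id = df$subject_id,
                                   cdr = df$cdr))
  colnames(se) <- df$subject_id
  new("NPCohort", se)
}
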