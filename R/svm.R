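#' Build a kernel configuration
#'
#' @param kind one of "linear", "quadratic", "rbf", "mlp".
#' @param sigma Gaussian RBF bandwidth (default 1; "rbf" only).
#' @param mlpScale the (p1, p2) scale of the sigmoid kernel
#'   tanh(p1 x.y + p2) (default (1, -1); "mlp" only).
#' @param cost soft-margin cost C (default 1).
#' @return A \linkS4class{KernelConfig}.
#' @export
kernelConfig <- function(kind = c("linear", "quadratic", "rbf", "mlp"),
                         sigma = 1, mlpScale = c(1, -1), cost = 1) {
  kind <- match.arg(kind)
  new("KernelConfig", kind = kind, sigma = sigma,
      mlpScale = as.numeric(mlpScale), cost = cost)
}

#' Evaluate a kernel function
#'
#' Computes k(x, y) for a pair of vectors: linear x.y, quadratic
#' (1 + x.y)^2, Gaussian RBF exp(-||x - y||^2 / (2 sigma^2)), or sigmoid
#' tanh(p1 x.y + p2).
#'
#' @param config a \linkS4class{KernelConfig}.
#' @param x,y numeric vectors of equal length.
#' @return The scalar kernel value.
#' @examples
#' kernelEval(kernelConfig("quadratic"), c(1, 1), c(1, 1))  # 9
#' @export
kernelEval <- function(config, x, y) {
  if (length(x) != length(y))
    stop("kernel arguments must have equal dimensionality")
  drop(.kernelMatrix(config, matrix(x, 1), matrix(y, 1)))
}

# Cross-kernel matrix K[i, j] = k(X[i, ], Y[j, ]); vectorized over rows.
.kernelMatrix <- function(config, X, Y) {
  G <- X %*% t(Y)
  switch(config@kind,
         linear = G,
         quadratic = (1 + G)^2,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
           exp(-pmax(d2, 0) / (2 * config@sigma^2))
         },
         mlp = tanh(config@mlpScale[1] * G + config@mlpScale[2]))
}

# Maps the package's kernel configurations onto the libsvm parameterization
# used by e1071::svm (the solver behind trainSVM).
.svmArgs <- function(config) {
  switch(config@kind,
         linear = list(kernel = "linear"),
         quadratic = list(kernel = "polynomial", degree = 2, gamma = 1,
                          coef0 = 1),
         rbf = list(kernel = "radial", gamma = 1 / (2 * config@sigma^2)),
         mlp = list(kernel = "sigmoid", gamma = config@mlpScale[1],
                    coef0 = config@mlpScale[2]))
}

#' Train a binary SVM
#'
#' Fits a soft-margin SVM on standardized features and exports the dual
#' solution, so the decision function
#' y(x) = sum_n w_n t_n k(x, x_n) + b is directly evaluable from the
#' returned object. Labels are +1 / -1 with +1 conventionally the
#' higher-impairment class, so sensitivity measures detection of
#' impairment.
#'
#' @param X subjects-by-features numeric matrix (no missing values).
#' @param y labels in {-1, +1} (numeric, or a factor coercible to it).
#' @param config a \linkS4class{KernelConfig}.
#' @return A \linkS4class{TrainedSVM}.
#' @examples
#' X <- rbind(c(1, 1), c(-1, -1)); y <- c(1, -1)
#' predictSVM(trainSVM(X, y, kernelConfig("linear")), X)  # 1 -1
#' @export
trainSVM <- function(X, y, config = kernelConfig("linear")) {
  X <- as.matrix(X)
  y <- as.numeric(as.character(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (anyNA(X)) stop("missing values in training matrix")
  # libsvm orients decision values toward the first class it encounters, so
  # order rows positive-class-first; the dual solution is permutation
  # invariant, this only pins the sign.
  ord <- order(y, decreasing = TRUE)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  yf <- factor(y, levels = c(1, -1))
  args <- c(list(x = X, y = yf, scale = FALSE, cost = config@cost),
            .svmArgs(config))
  fit <- tryCatch(do.call(e1071::svm, args), error = function(e)
    stop("SVM solver failure: ", conditionMessage(e), call. = FALSE))
  new("TrainedSVM",
      supports = unname(as.matrix(fit$SV)),
      weights = as.numeric(fit$coefs),
      bias = -fit$rho,
      kernel = config,
      features = colnames(X) %||% paste0("V", seq_len(ncol(X))))
}

#' Decision values and class predictions
#'
#' `decisionValues` evaluates y(x) = sum_n w_n t_n k(x, x_n) + b per row;
#' `predictSVM` returns sign(y(x)) as +1 / -1, with an exact zero assigned
#' to the positive class.
#'
#' @param model a \linkS4class{TrainedSVM}.
#' @param X subjects-by-features matrix with the model's feature count.
#' @return A numeric vector (decision values or +/-1 labels).
#' @export
decisionValues <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@supports))
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 ncol(model@supports), ncol(X)))
  drop(.kernelMatrix(model@kernel, X, model@supports) %*% model@weights) +
    model@bias
}

#' @rdname decisionValues
#' @export
predictSVM <- function(model, X) {
  ifelse(decisionValues(model, X) >= 0, 1, -1)
}

#' Serialize a trained SVM to JSON
#'
#' Writes supports, weights, bias and the kernel configuration; the decision
#' function is fully reconstructible from the file.
#'
#' @param model a \linkS4class{TrainedSVM}.
#' @param path JSON file path.
#' @export
writeTrainedSVM <- function(model, path) {
  k <- model@kernel
  jsonlite::write_json(list(
    kernel = list(kind = k@kind, sigma = k@sigma, mlp_scale = k@mlpScale,
                  cost = k@cost),
    features = model@features,
    supports = apply(model@supports, 1, identity, simplify = FALSE),
    weights = model@weights,
    bias = model@bias), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrainedSVM
#' @export
readTrainedSVM <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sup <- if (is.list(p$supports)) do.call(rbind, p$supports) else
    matrix(p$supports, nrow = length(p$weights))
  new("TrainedSVM", supports = sup, weights = p$weights, bias = p$bias,
      kernel = kernelConfig(p$kernel$kind, sigma = p$kernel$sigma,
                            mlpScale = p$kernel$mlp_scale,
                            cost = p$kernel$cost),
      features = p$features)
}

setMethod("show", "TrainedSVM", function(object) {
  cat(sprintf("TrainedSVM (%s kernel): %d support vectors over %d features\n",
              object@kernel@kind, nrow(object@supports),
              length(object@features)))
})

setMethod("show", "KernelConfig", function(object) {
  extra <- switch(object@kind,
                  rbf = sprintf(", sigma = %g", object@sigma),
                  mlp = sprintf(", scale = (%g, %g)", object@mlpScale[1],
                                object@mlpScale[2]),
                  "")
  cat(sprintf("KernelConfig: %s%s, cost = %g\n", object@kind, extra,
              object@cost))
})
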