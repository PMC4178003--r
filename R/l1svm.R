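#' Class-weighting penalties for an imbalanced outcome
#'
#' The misclassification penalty of one class is fixed at 1 and the other is
#' set to the ratio of negative to positive training samples, so that the
#' positive class is up-weighted when it is the rarer one. The convention can
#' be swapped.
#'
#' @param y Binary 0/1 labels (1 = positive/severe).
#' @param swap If `TRUE`, fix the positive-class penalty at 1 and set the
#'   negative-class penalty to `N_pos / N_neg` instead.
#' @return Named numeric vector `c(pos = , neg = )` with attribute
#'   `"convention"`.
#' @export
class_penalties <- function(y, swap = FALSE) {
  y <- as_binary_label(y)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_fmt("both classes must be present to derive penalties")
  }
  out <- if (!swap) c(pos = n_neg / n_pos, neg = 1.0)
         else c(pos = 1.0, neg = n_pos / n_neg)
  attr(out, "convention") <- if (!swap) "pos = N_neg/N_pos, neg = 1" else
    "pos = 1, neg = N_pos/N_neg"
  out
}

#' Fit a 1-norm (sparse) linear support vector machine
#'
#' Solves the class-weighted soft-margin linear program
#' \deqn{\min_{w,b,\xi} \|w\|_1 + C_{+}\sum_{i:y_i=+1}\xi_i +
#'       C_{-}\sum_{i:y_i=-1}\xi_i
#'       \quad \text{s.t.}\quad y_i (w \cdot x_i + b) \ge 1 - \xi_i,\ \xi_i \ge 0}
#' via the standard split \eqn{w = w^+ - w^-} as a dense linear program
#' (single-phase simplex; the slack variables provide the starting basis).
#' The L1 penalty drives irrelevant weights exactly to zero. Labels are
#' supplied as 0/1 and coded -1/+1 internally. Features are standardized to
#' zero mean and unit standard deviation before fitting (the stored
#' parameters let [predict.l1svm()] accept raw-unit data), unless
#' `normalize = FALSE`, in which case the input is taken as already
#' standardized.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary 0/1 labels.
#' @param penalties Named vector `c(pos=, neg=)`; defaults to
#'   [class_penalties()] of `y`.
#' @param normalize Standardize columns before fitting (default `TRUE`).
#' @param zero_tol Weights with absolute value below this are reported as
#'   exactly zero (default `1e-8`).
#' @return An object of class `l1svm` with elements `weights`, `bias`,
#'   `feature_names`, `center`, `scale`, `penalties`, and `diagnostics`
#'   (objective value, slacks, number of nonzero weights, solver status).
#' @export
l1svm <- function(x, y, penalties = NULL, normalize = TRUE, zero_tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_label(y)
  if (nrow(x) != length(y)) stop_fmt("x and y have different lengths")
  if (is.null(penalties)) penalties <- class_penalties(y)
  if (is.null(names(penalties))) names(penalties) <- c("pos", "neg")
  if (normalize) {
    nf <- normalize_features(x)
    xs <- nf$x
    center <- nf$params$mean
    scale <- nf$params$sd
  } else {
    xs <- x
    center <- setNames(rep(0, ncol(x)), colnames(x))
    scale <- setNames(rep(1, ncol(x)), colnames(x))
  }
  n <- nrow(xs); p <- ncol(xs)
  ys <- ifelse(y == 1L, 1, -1)
  # variables: u(p), v(p), b1, b2, xi(n)
  A <- cbind(xs * ys, -xs * ys, ys, -ys, diag(n))
  cc <- c(rep(1, 2 * p), 0, 0,
          ifelse(ys > 0, penalties[["pos"]], penalties[["neg"]]))
  sol <- svm_lp_solve(A, rep(1, n), cc)
  if (!identical(sol$status, "optimal")) {
    stop_fmt("LP solver did not converge (status: %s after %d iterations)",
             sol$status, sol$iterations)
  }
  z <- sol$z
  w <- z[1:p] - z[(p + 1):(2 * p)]
  b <- z[2 * p + 1] - z[2 * p + 2]
  xi <- z[(2 * p + 3):(2 * p + 2 + n)]
  w[abs(w) < zero_tol] <- 0
  names(w) <- colnames(x)
  obj <- sum(abs(w)) + penalties[["pos"]] * sum(xi[ys > 0]) +
    penalties[["neg"]] * sum(xi[ys < 0])
  structure(list(
    weights = w,
    bias = b,
    feature_names = colnames(x),
    center = center,
    scale = scale,
    penalties = c(pos = penalties[["pos"]], neg = penalties[["neg"]]),
    penalty_convention = attr(penalties, "convention") %||% "user-specified",
    diagnostics = list(objective = obj,
                       lp_objective = sol$objective,
                       slacks = xi,
                       n_nonzero_weights = sum(w != 0),
                       status = sol$status,
                       iterations = sol$iterations)
  ), class = "l1svm")
}

#' Build a linear severity model from explicit parameters
#'
#' Constructs an `l1svm` object directly from weights, normalization
#' parameters, and a bias, so that externally published decision functions
#' can be scored and compared like fitted models.
#'
#' @param weights Named numeric weight vector (on the standardized scale).
#' @param center,scale Per-feature mean and standard deviation (raw units).
#' @param bias Intercept of the decision function (standardized scale).
#' @param weight_se Optional standard errors of the weights.
#' @return An `l1svm` object.
#' @export
linear_severity_model <- function(weights, center, scale, bias = 0,
                                  weight_se = NULL) {
  stopifnot(length(weights) == length(center), length(center) == length(scale))
  if (any(scale <= 0)) stop_fmt("scale entries must be strictly positive")
  nm <- names(weights)
  structure(list(weights = weights, bias = bias, feature_names = nm,
                 center = setNames(as.numeric(center), nm),
                 scale = setNames(as.numeric(scale), nm),
                 penalties = NULL, penalty_convention = "external",
                 weight_se = weight_se, diagnostics = NULL),
            class = "l1svm")
}

#' Decision scores and class predictions from a sparse linear SVM
#'
#' The decision score of a raw-unit sample `x` is
#' `sum_i w_i * (x_i - mu_i) / sigma_i + b`; the predicted class is 1 exactly
#' when the score is greater than or equal to zero.
#'
#' @param object An `l1svm` model.
#' @param newdata Matrix, data.frame, or single named vector in raw units.
#' @param type `"score"` for decision values, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric scores or 0/1 integer labels, one per row.
#' @export
predict.l1svm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss)) stop_fmt("newdata lacks model features: %s",
                               paste(miss, collapse = ", "))
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  xs <- apply_normalization(newdata,
                            list(mean = object$center, sd = object$scale,
                                 feature_names = object$feature_names))
  score <- as.numeric(xs %*% object$weights + object$bias)
  if (type == "score") score else classify_score(score)
}

#' Threshold a severity score at zero
#'
#' @param score Numeric decision score(s).
#' @return 1 where `score >= 0`, else 0.
#' @export
classify_score <- function(score) as.integer(score >= 0)

#' @export
print.l1svm <- function(x, ...) {
  cat("Sparse (1-norm) linear SVM severity model\n")
  nz <- x$weights[x$weights != 0]
  cat(sprintf("  %d features, %d nonzero weights, bias %.4g\n",
              length(x$weights), sum(x$weights != 0), x$bias))
  if (length(nz)) {
    for (nm in names(sort(-abs(nz)))) {
      cat(sprintf("    %-14s %+.4f\n", nm, nz[[nm]]))
    }
  }
  if (!is.null(x$penalties)) {
    cat(sprintf("  penalties: C_pos = %.4g, C_neg = %.4g (%s)\n",
                x$penalties[["pos"]], x$penalties[["neg"]],
                x$penalty_convention))
  }
  invisible(x)
}

#' @export
coef.l1svm <- function(object, ...) c("(bias)" = object$bias, object$weights)

#' @export
summary.l1svm <- function(object, ...) {
  print(object)
  if (!is.null(object$diagnostics)) {
    d <- object$diagnostics
    cat(sprintf("  objective %.6g, max slack %.4g, solver %s (%d iterations)\n",
                d$objective, max(d$slacks), d$status, d$iterations))
  }
  invisible(object)
}

#' Serialize a linear severity model to JSON
#'
#' @param model An `l1svm` object.
#' @param path Output path.
#' @export
write_l1svm <- function(model, path) {
  obj <- list(feature_names = model$feature_names,
              weights = as.numeric(model$weights),
              bias = model$bias,
              means = as.numeric(model$center),
              sds = as.numeric(model$scale),
              penalties = if (!is.null(model$penalties))
                as.list(model$penalties) else NULL,
              penalty_convention = model$penalty_convention,
              note = "1-norm linear SVM; weights act on standardized features")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear severity model from JSON
#'
#' @param path Path written by [write_l1svm()].
#' @return An `l1svm` object.
#' @export
read_l1svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- linear_severity_model(
    weights = setNames(as.numeric(obj$weights), obj$feature_names),
    center = obj$means, scale = obj$sds, bias = obj$bias)
  if (!is.null(obj$penalties)) {
    m$penalties <- unlist(obj$penalties)
    m$penalty_convention <- obj$penalty_convention
  }
  m
}
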