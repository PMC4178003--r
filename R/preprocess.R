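#' Column-standardize a feature matrix
#'
#' Centers every column to zero mean and scales it to unit sample standard
#' deviation (n - 1 denominator), returning both the standardized matrix and
#' the removed location/scale so that new samples can be mapped onto the same
#' scale (see [apply_normalization()]).
#'
#' @param x Numeric matrix (samples in rows, named columns).
#' @return A list with `x` (standardized matrix) and `params`, a list holding
#'   `mean`, `sd` and `feature_names`.
#' @export
normalize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_fmt("need at least 2 rows to normalize")
  if (anyNA(x)) stop_fmt("feature matrix contains missing values")
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  degenerate <- which(sdv <= 0 | !is.finite(sdv))
  if (length(degenerate)) {
    stop_fmt("constant column(s) cannot be normalized: %s",
             paste(colnames(x)[degenerate] %||% degenerate, collapse = ", "))
  }
  params <- list(mean = mu, sd = sdv, feature_names = colnames(x))
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), params = params)
}

#' Apply stored normalization parameters to new data
#'
#' @param x Numeric matrix or vector in raw units; column names (if present)
#'   must match the parameter names.
#' @param params Normalization parameters as produced by
#'   [normalize_features()].
#' @return `(x - mean) / sd`, columnwise.
#' @export
apply_normalization <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(params$feature_names)) {
    if (!identical(colnames(x), params$feature_names)) {
      if (!all(params$feature_names %in% colnames(x))) {
        stop_fmt("feature names do not match normalization parameters")
      }
      x <- x[, params$feature_names, drop = FALSE]
    }
  }
  if (ncol(x) != length(params$mean)) {
    stop_fmt("feature count (%d) does not match parameters (%d)",
             ncol(x), length(params$mean))
  }
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}

#' Invert a normalization
#'
#' @inheritParams apply_normalization
#' @return `x * sd + mean`, columnwise.
#' @export
invert_normalization <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$sd, "*"), 2, params$mean, "+")
}

#' Random one-third test split
#'
#' Draws `round(n / 3)` test indices uniformly without replacement; the
#' remaining rows form the training set.
#'
#' @param n Number of rows (at least 3).
#' @param seed Integer seed.
#' @return A list with `train`, `test` (disjoint index vectors covering
#'   `1:n`) and `seed`.
#' @export
split_train_test <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop_fmt("need n >= 3 to split, got %s", n)
  n_test <- as.integer(round(n / 3))
  test <- sort(with_seed(seed, sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test, seed = as.integer(seed))
}

#' Per-group correlation matrices
#'
#' Pearson correlation of every variable pair, computed separately within the
#' two label groups (the data behind group-wise correlation heatmaps).
#'
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 labels, one per row of `x`.
#' @return A list with elements `"0"` and `"1"`, each a p x p correlation
#'   matrix.
#' @export
group_correlations <- function(x, y) {
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (nrow(x) != length(y)) stop_fmt("x and y have different lengths")
  out <- lapply(c(0L, 1L), function(g) {
    rows <- which(y == g)
    if (length(rows) < 3L) {
      stop_fmt("group %d has fewer than 3 rows; correlations undefined", g)
    }
    cor(x[rows, , drop = FALSE])
  })
  names(out) <- c("0", "1")
  out
}
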