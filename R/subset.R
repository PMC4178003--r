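# Covariance summaries used by the subset search: feature covariance matrix,
# feature-outcome covariances, outcome variance.
subset_moments <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_fmt("x and y have different lengths")
  list(C = cov(x), s = as.numeric(cov(x, y)), vy = var(y))
}

#' Canonical correlation of a feature subset with a binary outcome
#'
#' With a one-dimensional outcome the first canonical correlation between a
#' feature set and the outcome equals the multiple correlation coefficient,
#' i.e. the square root of the least-squares R-squared of the outcome on the
#' features plus an intercept. Rank-deficient subsets are handled by a
#' pseudo-inverse (singular values below `1e-10` of the largest dropped),
#' giving the supremum correlation over the column space.
#'
#' @param x Numeric matrix restricted to the candidate subset (columns).
#' @param y Binary 0/1 outcome, one entry per row; both classes must occur.
#' @return The canonical correlation, a value in `[0, 1]`.
#' @export
canonical_correlation <- function(x, y) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop_fmt("empty feature subset")
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop_fmt("outcome must contain both classes")
  if (nrow(x) <= ncol(x)) {
    stop_fmt("underdetermined: n (%d) must exceed subset size (%d)",
             nrow(x), ncol(x))
  }
  mo <- subset_moments(x, y)
  r2 <- subset_rsq_cpp(mo$C, mo$s, mo$vy, seq_len(ncol(x)) - 1L)
  sqrt(r2)
}

#' Exhaustive best subset of a given size
#'
#' Enumerates every size-`k` feature subset and returns the one maximizing
#' the canonical correlation with the outcome. Ties are broken in favor of
#' the lexicographically smallest feature-index set.
#'
#' @param x Numeric feature matrix with named columns.
#' @param y Binary 0/1 outcome.
#' @param k Subset size, `1 <= k <= ncol(x)`.
#' @return A list with `subset` (column indices), `names`, and `corr`.
#' @export
best_subset_of_size <- function(x, y, k) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > ncol(x)) {
    stop_fmt("k must be between 1 and %d, got %s", ncol(x), k)
  }
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop_fmt("outcome must contain both classes")
  mo <- subset_moments(x, y)
  res <- best_subset_cpp(mo$C, mo$s, mo$vy, k)
  list(subset = res$subset,
       names = colnames(x)[res$subset],
       corr = sqrt(res$rsq))
}

#' Stepwise best-subset trace
#'
#' Runs the exhaustive search for every subset size `k = 1..k_max` and
#' reports, per step, the correlation, the features entering, and the
#' features leaving relative to the previous step (a best subset of size k
#' need not contain the best subset of size k - 1, so several features may
#' enter and leave at once).
#'
#' @inheritParams best_subset_of_size
#' @param k_max Largest subset size to trace.
#' @return A data.frame of class `selection_trace` with columns `dim`,
#'   `corr`, `entering`, `leaving`, `members` (the latter three are
#'   comma-separated name lists).
#' @export
stepwise_trace <- function(x, y, k_max = ncol(x)) {
  x <- as.matrix(x)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > ncol(x)) stop_fmt("k_max out of range")
  prev <- character(0)
  rows <- vector("list", k_max)
  members_list <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    bs <- best_subset_of_size(x, y, k)
    entering <- setdiff(bs$names, prev)
    leaving <- setdiff(prev, bs$names)
    rows[[k]] <- data.frame(
      dim = k, corr = bs$corr,
      entering = paste(entering, collapse = ", "),
      leaving = paste(leaving, collapse = ", "),
      members = paste(bs$names, collapse = ", "),
      stringsAsFactors = FALSE)
    members_list[[k]] <- bs$names
    prev <- bs$names
  }
  out <- do.call(rbind, rows)
  attr(out, "members") <- members_list
  class(out) <- c("selection_trace", "data.frame")
  out
}

#' Greedy forward selection
#'
#' Adds, at each step, the single feature that maximizes the canonical
#' correlation of the augmented set; features are never removed. Ties are
#' broken by the smallest column index.
#'
#' @inheritParams stepwise_trace
#' @return A data.frame with columns `dim`, `corr`, `feature` (the feature
#'   added at each step); `attr(, "order")` carries the ordered index vector.
#' @export
forward_selection <- function(x, y, k_max = ncol(x)) {
  x <- as.matrix(x)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > ncol(x)) stop_fmt("k_max out of range")
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop_fmt("outcome must contain both classes")
  mo <- subset_moments(x, y)
  chosen <- integer(0)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    cand <- setdiff(seq_len(ncol(x)), chosen)
    r2 <- vapply(cand, function(j) {
      subset_rsq_cpp(mo$C, mo$s, mo$vy, c(chosen, j) - 1L)
    }, numeric(1))
    j_best <- cand[which.max(r2)]  # which.max takes the first (smallest index)
    chosen <- c(chosen, j_best)
    rows[[k]] <- data.frame(dim = k, corr = sqrt(max(r2)),
                            feature = colnames(x)[j_best] %||% as.character(j_best),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "order") <- chosen
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Stepwise best-subset selection (canonical correlation with outcome)\n")
  print.data.frame(x[, c("dim", "corr", "entering", "leaving")], row.names = FALSE, ...)
  invisible(x)
}

# Members of the best subset at size k from a trace.
trace_members <- function(trace, k) attr(trace, "members")[[k]]
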