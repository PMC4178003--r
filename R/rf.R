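#' Grow a random forest for biomarker ranking
#'
#' Wraps [randomForest::randomForest()] (Breiman's CART-forest: each tree on
#' a same-size bootstrap resample, splits chosen from a random feature subset
#' of size `floor(sqrt(p))` by default, Gini criterion) keeping the per-tree
#' in-bag counts and tree structures so that out-of-bag permutation
#' importance can be computed directly by [mda_importance()].
#'
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @return An object of class `panel_forest` with the fitted forest, the
#'   extracted tree matrices, the training data, in-bag counts, OOB majority
#'   predictions, and OOB accuracy.
#' @export
panel_forest <- function(x, y, n_trees = 1000L, seed = 1L,
                         mtry = max(1L, floor(sqrt(ncol(x))))) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop_fmt("both classes must be present")
  yf <- factor(y, levels = c(0L, 1L))
  rf <- with_seed(seed, randomForest::randomForest(
    x = x, y = yf, ntree = as.integer(n_trees), mtry = mtry,
    nodesize = 1L, keep.forest = TRUE, keep.inbag = TRUE))
  trees <- lapply(seq_len(rf$ntree), function(t) {
    unname(as.matrix(randomForest::getTree(rf, t, labelVar = FALSE)))
  })
  inbag <- rf$inbag
  storage.mode(inbag) <- "integer"
  # untouched traversal establishes per-tree baseline accuracy and OOB votes
  base <- with_seed(seed, mda_oob_cpp(trees[1], x, y + 1L,
                                      inbag[, 1, drop = FALSE]))
  structure(list(rf = rf, trees = trees, x = x, y = y, inbag = inbag,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 mtry = mtry),
            class = "panel_forest")
}

#' @export
print.panel_forest <- function(x, ...) {
  cat(sprintf("Random forest for biomarker ranking: %d trees, mtry %d, seed %d\n",
              x$n_trees, x$mtry, x$seed))
  cat(sprintf("  OOB error (forest): %.3f\n", tail(x$rf$err.rate[, "OOB"], 1)))
  invisible(x)
}

#' Out-of-bag permutation importance (mean decrease in accuracy)
#'
#' For every tree, compares the tree's accuracy on its untouched out-of-bag
#' rows with its accuracy after randomly permuting one feature's values
#' within those rows; the mean drop over trees is that feature's MDA.
#' Trees with an empty OOB set are skipped (and counted). Gini importance is
#' reported alongside for reference but the ranking is by MDA.
#'
#' @param forest A [panel_forest()] object.
#' @param seed Seed for the permutations.
#' @return A data.frame of class `importance_ranking` with columns `feature`,
#'   `mda`, `rank` (ordered by decreasing MDA), attribute `gini` carrying the
#'   forest's mean-decrease-in-Gini, plus `oob_accuracy`, `n_trees`, `seed`.
#' @export
mda_importance <- function(forest, seed = forest$seed) {
  stopifnot(inherits(forest, "panel_forest"))
  res <- with_seed(seed, mda_oob_cpp(forest$trees, forest$x,
                                     forest$y + 1L, forest$inbag))
  mda <- setNames(res$mda, colnames(forest$x))
  ord <- order(-mda)
  out <- data.frame(feature = names(mda)[ord], mda = unname(mda[ord]),
                    rank = seq_along(mda), stringsAsFactors = FALSE)
  oob_ok <- !is.na(res$oob_pred)
  attr(out, "oob_accuracy") <- mean((res$oob_pred - 1L)[oob_ok] == forest$y[oob_ok])
  attr(out, "gini") <- forest$rf$importance[, "MeanDecreaseGini"]
  attr(out, "base_accuracy") <- res$base_accuracy
  attr(out, "skipped_trees") <- res$skipped_trees
  attr(out, "n_trees") <- forest$n_trees
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("OOB permutation importance (%d trees, seed %d); OOB accuracy %.3f\n",
              attr(x, "n_trees"), attr(x, "seed"), attr(x, "oob_accuracy")))
  df <- data.frame(rank = x$rank, feature = x$feature,
                   mda = sprintf("%.4f", x$mda))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
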