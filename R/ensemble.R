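#' Bagged ensemble of sparse linear SVMs
#'
#' Fits `B` 1-norm SVMs on bootstrap resamples (same size as the training
#' set, drawn with replacement; resamples missing a class are redrawn) and
#' aggregates them by averaging weight vectors and biases. Because the
#' members are linear, the aggregate decision score equals the mean of the
#' member scores for every input. Features are standardized once on the full
#' training set so all members share a scale.
#'
#' @param x Numeric feature matrix (raw units).
#' @param y Binary 0/1 labels.
#' @param B Number of bootstrap members (default 50).
#' @param seed Integer seed.
#' @param penalties Optional penalty pair; defaults to [class_penalties()]
#'   recomputed on each resample.
#' @param max_redraws Redraw budget for single-class resamples (default 100).
#' @return An object of class `l1svm_bag`: the aggregate `l1svm` model plus
#'   the member list.
#' @export
l1svm_bag <- function(x, y, B = 50L, seed = 1L, penalties = NULL,
                      max_redraws = 100L) {
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop_fmt("both classes must be present")
  B <- as.integer(B)
  if (B < 1L) stop_fmt("B must be at least 1")
  nf <- normalize_features(x)
  n <- nrow(x)
  members <- with_seed(seed, {
    lapply(seq_len(B), function(bi) {
      for (attempt in seq_len(max_redraws)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) {
          pen <- penalties %||% class_penalties(y[idx])
          fit <- l1svm(nf$x[idx, , drop = FALSE], y[idx],
                       penalties = pen, normalize = FALSE)
          # members act on the shared standardized scale
          fit$center <- nf$params$mean
          fit$scale <- nf$params$sd
          return(fit)
        }
      }
      stop_fmt("could not draw a two-class bootstrap resample in %d attempts",
               max_redraws)
    })
  })
  W <- vapply(members, function(m) m$weights, numeric(ncol(x)))
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  aggregate <- linear_severity_model(
    weights = setNames(rowMeans(W), colnames(x)),
    center = nf$params$mean, scale = nf$params$sd,
    bias = mean(vapply(members, function(m) m$bias, numeric(1))))
  aggregate$penalty_convention <- "mean of bagged members"
  structure(list(aggregate = aggregate, members = members, B = B,
                 seed = as.integer(seed)),
            class = "l1svm_bag")
}

#' @export
print.l1svm_bag <- function(x, ...) {
  cat(sprintf("Bagged 1-norm SVM ensemble (B = %d, seed = %d)\n", x$B, x$seed))
  print(x$aggregate)
  invisible(x)
}

#' Predict from a bagged SVM ensemble
#'
#' @param object An `l1svm_bag` object.
#' @param newdata Raw-unit matrix or data.frame.
#' @param type `"score"`, `"class"` (mean decision function thresholded at
#'   zero), or `"vote"` (majority vote of member classes).
#' @param ... Unused.
#' @export
predict.l1svm_bag <- function(object, newdata,
                              type = c("score", "class", "vote"), ...) {
  type <- match.arg(type)
  if (type %in% c("score", "class")) {
    return(predict(object$aggregate, newdata, type = type))
  }
  votes <- vapply(object$members, function(m) predict(m, newdata, type = "class"),
                  integer(nrow(as.matrix(newdata))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  as.integer(rowMeans(votes) > 0.5)
}

#' Diagnostic prediction measures
#'
#' Computes sensitivity (TPR), specificity (TNR), and the positive/negative
#' predictive values from predicted and true binary labels. A measure whose
#' denominator is zero is reported as `NaN`, never silently as 0.
#'
#' @param predictions 0/1 predicted labels.
#' @param truths 0/1 true labels.
#' @return Named numeric vector `c(TPR, TNR, PPV, NPV)`.
#' @export
prediction_measures <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop_fmt("predictions and truths have different lengths")
  }
  pr <- as_binary_label(predictions)
  tr <- as_binary_label(truths)
  tp <- sum(pr == 1L & tr == 1L)
  tn <- sum(pr == 0L & tr == 0L)
  fp <- sum(pr == 1L & tr == 0L)
  fn <- sum(pr == 0L & tr == 1L)
  ratio <- function(a, b) if (b == 0) NaN else a / b
  c(TPR = ratio(tp, tp + fn), TNR = ratio(tn, tn + fp),
    PPV = ratio(tp, tp + fp), NPV = ratio(tn, tn + fn))
}

#' Repeated random-split evaluation of a biomarker subset
#'
#' For each of `R` repeats, draws a random one-third test split, fits a
#' bagged 1-norm SVM ensemble on the remaining two thirds restricted to the
#' chosen subset, and scores the held-out third. Reports the mean and
#' standard error (SD over defined repeats divided by the square root of
#' their count) of TPR, TNR, PPV, and NPV.
#'
#' @param x Raw-unit feature matrix.
#' @param y Binary 0/1 labels.
#' @param subset Column names or indices to evaluate (default: all).
#' @param B Ensemble size per repeat (default 50).
#' @param R Number of random splits (default 100).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @param normalization `"global"` standardizes on the full matrix before
#'   splitting (matching a pipeline that normalizes once up front);
#'   `"train-only"` re-estimates the standardization on each training split
#'   (leakage-safe variant).
#' @param max_redraws Redraw budget for single-class training splits.
#' @return A `panel_evaluation` data.frame with one row per measure
#'   (`measure`, `mean`, `se`, `n_undefined`) and attributes `R`, `B`,
#'   `subset`, `seed`, `repeats` (the R x 4 per-repeat matrix).
#' @export
repeated_evaluation <- function(x, y, subset = NULL, B = 50L, R = 100L,
                                seed = 1L,
                                normalization = c("global", "train-only"),
                                max_redraws = 10L) {
  normalization <- match.arg(normalization)
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (nrow(x) < 6L) stop_fmt("need at least 6 rows for repeated evaluation")
  if (!is.null(subset)) {
    x <- x[, subset, drop = FALSE]
  }
  if (ncol(x) < 1L) stop_fmt("empty feature subset")
  if (normalization == "global") {
    # paper-faithful: standardize once, before any splitting
    x <- normalize_features(x)$x
  }
  seeds <- derive_seeds(seed, R * (max_redraws + 1L))
  si <- 0L
  res <- matrix(NA_real_, R, 4, dimnames = list(NULL, c("TPR", "TNR", "PPV", "NPV")))
  pos_rate <- numeric(R)
  prevalence <- numeric(R)
  redrawn <- 0L
  for (r in seq_len(R)) {
    for (attempt in seq_len(max_redraws)) {
      si <- si + 1L
      plan <- split_train_test(nrow(x), seeds[si])
      if (length(unique(y[plan$train])) == 2L) break
      redrawn <- redrawn + 1L
      if (attempt == max_redraws) {
        stop_fmt("could not draw a two-class training split in %d attempts",
                 max_redraws)
      }
    }
    bag <- l1svm_bag(x[plan$train, , drop = FALSE], y[plan$train],
                     B = B, seed = seeds[si])
    pred <- predict(bag, x[plan$test, , drop = FALSE], type = "class")
    res[r, ] <- prediction_measures(pred, y[plan$test])
    pos_rate[r] <- mean(pred == 1L)
    prevalence[r] <- mean(y[plan$test] == 1L)
  }
  summarize <- function(v) {
    def <- v[is.finite(v)]
    c(mean = if (length(def)) mean(def) else NaN,
      se = if (length(def) > 1L) sd(def) / sqrt(length(def)) else
        if (length(def) == 1L) 0 else NaN,
      n_undefined = sum(!is.finite(v)))
  }
  sm <- t(apply(res, 2, summarize))
  out <- data.frame(measure = rownames(sm), mean = sm[, "mean"],
                    se = sm[, "se"], n_undefined = as.integer(sm[, "n_undefined"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "R") <- R
  attr(out, "B") <- B
  attr(out, "subset") <- colnames(x)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "repeats") <- res
  attr(out, "pred_pos_rate") <- mean(pos_rate)
  attr(out, "prevalence") <- mean(prevalence)
  attr(out, "redrawn_splits") <- redrawn
  class(out) <- c("panel_evaluation", "data.frame")
  out
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("Repeated-split evaluation (R = %d, B = %d) of {%s}\n",
              attr(x, "R"), attr(x, "B"),
              paste(attr(x, "subset"), collapse = ", ")))
  df <- data.frame(measure = x$measure,
                   mean = sprintf("%.3f", x$mean),
                   se = sprintf("%.4f", x$se))
  print.data.frame(df, row.names = FALSE)
  if (attr(x, "R") < 2L) cat("  note: SEs are degenerate with R < 2\n")
  invisible(x)
}

#' Prediction measures as a function of panel size
#'
#' Evaluates nested subsets of increasing size taken from a feature ranking
#' (a [forward_selection()] result, a [stepwise_trace()], or a character
#' vector) with [repeated_evaluation()], producing the data behind
#' measure-versus-panel-size curves.
#'
#' @inheritParams repeated_evaluation
#' @param ranking Feature ranking; for a `selection_trace` the exact member
#'   set at each size is used (it need not be nested).
#' @param k_max Largest panel size (default: full ranking).
#' @return A data.frame with columns `k`, `measure`, `mean`, `se`,
#'   `n_undefined`, `members`.
#' @export
subset_size_curve <- function(x, y, ranking, B = 50L, R = 100L, seed = 1L,
                              k_max = NULL, normalization = "global") {
  x <- as.matrix(x)
  members_at <- function(k) {
    if (inherits(ranking, "selection_trace")) {
      trace_members(ranking, k)
    } else if (is.character(ranking)) {
      ranking[seq_len(k)]
    } else if (!is.null(attr(ranking, "order"))) {
      colnames(x)[attr(ranking, "order")[seq_len(k)]]
    } else {
      stop_fmt("unsupported ranking object")
    }
  }
  km <- k_max %||% if (inherits(ranking, "selection_trace")) nrow(ranking)
    else if (is.character(ranking)) length(ranking)
    else length(attr(ranking, "order"))
  seeds <- derive_seeds(seed, km)
  rows <- lapply(seq_len(km), function(k) {
    mem <- members_at(k)
    ev <- repeated_evaluation(x, y, subset = mem, B = B, R = R,
                              seed = seeds[k], normalization = normalization)
    data.frame(k = k, measure = ev$measure, mean = ev$mean, se = ev$se,
               n_undefined = ev$n_undefined,
               members = paste(mem, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "B") <- B
  attr(out, "R") <- R
  attr(out, "seed") <- as.integer(seed)
  out
}
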