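test_that("canonical correlation with one outcome is the multiple correlation", {
  # a column equal to the outcome gives correlation 1
  y <- rep(c(0L, 1L), 10)
  expect_equal(canonical_correlation(matrix(as.numeric(y)), y), 1)

  # single columns reduce to |Pearson r|
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(rnorm(30), ncol = 1)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(canonical_correlation(x, y), abs(cor(x[, 1], y)),
                 tolerance = 1e-12)
  }

  # multi-column subsets match an independent least-squares fit
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- rbinom(40, 1, 0.5)
  expect_equal(canonical_correlation(x, y), ols_multiple_correlation(x, y),
               tolerance = 1e-10)
  # and the first canonical correlation from stats::cancor
  expect_equal(canonical_correlation(x, y),
               stats::cancor(x, matrix(as.numeric(y)))$cor[1],
               tolerance = 1e-10)
})

test_that("degenerate subsets raise the documented errors", {
  y <- rep(c(0L, 1L), 10)
  x <- matrix(rnorm(20), ncol = 1)
  expect_error(canonical_correlation(x[, 0, drop = FALSE], y), "empty")
  expect_error(canonical_correlation(matrix(rnorm(4), 2, 2), c(0L, 1L)),
               "underdetermined")
  expect_error(canonical_correlation(x, rep(1L, 20)), "both classes")
})

test_that("rank-deficient subsets fall back to the column-space supremum", {
  set.seed(4)
  y <- rbinom(50, 1, 0.5)
  a <- rnorm(50)
  x <- cbind(a, 2 * a)  # rank 1
  expect_equal(canonical_correlation(x, y), abs(cor(a, y)), tolerance = 1e-8)
})

test_that("exhaustive search agrees with brute-force enumeration", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40; p <- 6
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, 0.5)
    for (k in 1:p) {
      got <- best_subset_of_size(x, y, k)
      want <- brute_force_best_subset(x, y, k)
      expect_equal(sort(got$subset), sort(want$subset))
      expect_equal(got$corr, want$corr, tolerance = 1e-10)
    }
  }
  # k = p returns the full model
  set.seed(10)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(30, 1, 0.5)
  full <- best_subset_of_size(x, y, 4)
  expect_equal(sort(full$subset), 1:4)
  expect_equal(full$corr, ols_multiple_correlation(x, y), tolerance = 1e-10)
  expect_error(best_subset_of_size(x, y, 0), "between")
  expect_error(best_subset_of_size(x, y, 5), "between")
})

test_that("exact ties break toward the lexicographically smallest set", {
  set.seed(6)
  y <- rep(c(0L, 1L), 20)
  a <- y + rnorm(40, sd = 0.3)  # clearly the strongest single feature
  x <- cbind(first = a, second = a, other = rnorm(40))
  bs <- best_subset_of_size(x, y, 1)
  expect_equal(bs$subset, 1L)
  # duplicated columns tie at every size; the smaller index pair wins
  bs2 <- best_subset_of_size(x, y, 2)
  expect_equal(bs2$subset[1], 1L)
})

test_that("stepwise trace reports entering and leaving features", {
  ni <- nested_instance()
  tr <- stepwise_trace(ni$x, ni$y, 4)
  expect_s3_class(tr, "selection_trace")
  expect_true(all(tr$leaving == ""))  # nested optima never drop features
  expect_true(all(diff(tr$corr) >= -1e-10))

  si <- suppressor_instance()
  tr2 <- stepwise_trace(si$x, si$y, 3)
  expect_equal(trace_members(tr2, 1), "x1")
  expect_identical(sort(trace_members(tr2, 2)), c("x2", "x3"))
  expect_match(tr2$leaving[2], "x1")
  # verified independently by brute force
  expect_equal(sort(brute_force_best_subset(si$x, si$y, 2)$subset), c(2L, 3L))
})

test_that("trace correlations are non-decreasing on random instances", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 50; p <- 7
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, 0.5)
    tr <- stepwise_trace(x, y, p)
    expect_true(all(diff(tr$corr) >= -1e-10))
    # set algebra invariant: members(k) = members(k-1) + entering - leaving
    for (k in 2:p) {
      rebuilt <- setdiff(union(trace_members(tr, k - 1),
                               strsplit(tr$entering[k], ", ")[[1]]),
                         strsplit(tr$leaving[k], ", ")[[1]])
      expect_setequal(rebuilt[rebuilt != ""], trace_members(tr, k))
    }
  }
})

test_that("forward selection is greedy and can diverge from exhaustive search", {
  si <- suppressor_instance()
  fs <- forward_selection(si$x, si$y, 3)
  # first pick maximizes the single-feature correlation
  singles <- abs(cor(si$x, si$y))
  expect_equal(fs$feature[1], colnames(si$x)[which.max(singles)])
  # greedy keeps x1, exhaustive drops it at k = 2
  expect_true("x1" %in% attr(fs, "order")[1:2] |
                fs$feature[1] == "x1")
  tr <- stepwise_trace(si$x, si$y, 2)
  expect_false(setequal(colnames(si$x)[attr(fs, "order")[1:2]],
                        trace_members(tr, 2)))

  # on nested instances greedy equals exhaustive at every size
  ni <- nested_instance()
  fs2 <- forward_selection(ni$x, ni$y, 4)
  tr2 <- stepwise_trace(ni$x, ni$y, 4)
  for (k in 1:4) {
    expect_setequal(colnames(ni$x)[attr(fs2, "order")[1:k]],
                    trace_members(tr2, k))
  }
})

test_that("planted markers dominate the selection on synthetic cohorts", {
  # qualitative recovery at the study scale: the severe-shifted angiopoietin
  # axis leads the search and pure noise never reaches the top of the trace
  hits_a2 <- 0
  for (s in 1:5) {
    f <- planted_features(seed = s)
    xn <- normalize_features(f$x)$x
    bs <- best_subset_of_size(xn, f$y, 3)
    expect_false(any(c("g-Noise", "u-Noise") %in% bs$names))
    if (any(c("Ang-2", "Ang-2/Ang-1") %in% bs$names)) hits_a2 <- hits_a2 + 1
  }
  expect_gte(hits_a2, 4)
})
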