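test_that("class penalties follow the prevalence ratio", {
  y <- c(rep(0L, 20), rep(1L, 10))
  pen <- class_penalties(y)
  expect_equal(unname(pen["pos"]), 2)
  expect_equal(unname(pen["neg"]), 1)
  swapped <- class_penalties(y, swap = TRUE)
  expect_equal(unname(swapped["pos"]), 1)
  expect_equal(unname(swapped["neg"]), 0.5)
  expect_equal(as.numeric(class_penalties(rep(c(0L, 1L), 10))), c(1, 1))
  expect_error(class_penalties(rep(1L, 5)), "both classes")
})

test_that("the two-point instance is solved exactly", {
  x <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(0L, 1L)
  fit <- l1svm(x, y, penalties = c(pos = 1, neg = 1), normalize = FALSE)
  expect_lt(max(fit$diagnostics$slacks), 1e-9)
  expect_lte(abs(fit$weights[["f"]]), 1 + 1e-6)
  expect_equal(fit$diagnostics$objective, 1, tolerance = 1e-8)
  # margin constraints are active: y * (w x + b) = 1 at both points
  expect_equal(as.numeric(c(-1, 1) * (fit$weights * c(-1, 1) + fit$bias)),
               c(1, 1), tolerance = 1e-8)
  expect_equal(predict(fit, x, type = "class"), c(0L, 1L))
})

test_that("an identically zero feature gets weight exactly zero", {
  set.seed(8)
  x <- cbind(signal = rnorm(30), dead = 0)
  y <- as.integer(x[, "signal"] + rnorm(30, sd = 0.3) > 0)
  fit <- l1svm(x, y, normalize = FALSE)
  expect_identical(fit$weights[["dead"]], 0)
})

test_that("separable instances are solved to zero training error", {
  set.seed(11)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0L, 1L), each = 20)
  x[y == 1, 1] <- x[y == 1, 1] + 6
  fit <- l1svm(x, y, normalize = FALSE)
  expect_equal(predict(fit, x, type = "class"), y)
  expect_lt(max(fit$diagnostics$slacks), 1e-8)
  oracle <- scipy_svm_objective(x, y, fit$penalties)
  expect_equal(fit$diagnostics$objective, oracle, tolerance = 1e-6)
})

test_that("objective values match the external LP oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- 10 + 2 * i; p <- 2 + (i %% 3)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    fit <- l1svm(x, y, normalize = FALSE)
    oracle <- scipy_svm_objective(x, y, fit$penalties)
    expect_equal(fit$diagnostics$objective, oracle, tolerance = 1e-6)
    # diagnostics identity: reported objective = ||w||_1 + weighted slacks
    expect_equal(fit$diagnostics$objective, fit$diagnostics$lp_objective,
                 tolerance = 1e-6)
    expect_true(all(fit$diagnostics$slacks >= -1e-9))
  }
})

test_that("the solution beats random feasible candidates", {
  set.seed(13)
  n <- 20; p <- 3
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  fit <- l1svm(x, y, penalties = c(pos = 1, neg = 1), normalize = FALSE)
  ys <- ifelse(y == 1, 1, -1)
  for (i in 1:100) {
    w <- rnorm(p); b <- rnorm(1)
    xi <- pmax(0, 1 - ys * (x %*% w + b))   # minimal feasible slacks
    cand <- sum(abs(w)) + sum(xi)
    expect_gte(cand, fit$diagnostics$objective - 1e-9)
  }
})

test_that("stronger penalties never reduce sparsity when scaled down", {
  set.seed(17)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] - x[, 2] + rnorm(50, sd = 0.8) > 0)
  fit_hi <- l1svm(x, y, penalties = c(pos = 1, neg = 1), normalize = FALSE)
  fit_lo <- l1svm(x, y, penalties = c(pos = 0.1, neg = 0.1), normalize = FALSE)
  expect_lte(fit_lo$diagnostics$n_nonzero_weights,
             fit_hi$diagnostics$n_nonzero_weights)
})

test_that("fitted weights carry the clinical signs on planted cohorts", {
  ok <- 0
  for (s in 1:20) {
    f <- planted_features(seed = s)
    fit <- l1svm(f$x[, panel_trio], f$y)
    w <- fit$weights
    if (w[["Ang-2"]] > 0 && w[["Ang-1"]] < 0 && w[["HCO3"]] < 0) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("decision scores are the standardized linear form", {
  m <- linear_severity_model(
    weights = c(a = 2, b = -1), center = c(10, 20), scale = c(5, 4), bias = 0)
  expect_equal(predict(m, c(a = 10, b = 20)), 0)
  expect_equal(predict(m, c(a = 15, b = 20)), 2)
  expect_equal(predict(m, c(a = 10, b = 24)), -1)
  expect_error(predict(m, data.frame(a = 1)), "lacks model features")
  # classification boundary: scores straddling zero
  expect_identical(classify_score(c(-1e-12, 0, 2.7, -3)), c(0L, 1L, 1L, 0L))
})

test_that("models serialize to JSON and back", {
  f <- planted_features(seed = 4)
  fit <- l1svm(f$x[, panel_trio], f$y)
  tf <- tempfile(fileext = ".json")
  write_l1svm(fit, tf)
  back <- read_l1svm(tf)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$bias, fit$bias)
  expect_equal(unname(back$center), unname(fit$center))
  expect_equal(unname(back$scale), unname(fit$scale))
  x_new <- f$x[1:5, panel_trio]
  expect_equal(predict(back, x_new), predict(fit, x_new))
})
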