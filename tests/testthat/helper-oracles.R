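# Independent oracles and small data builders shared across the test files.

# Multiple correlation via an ordinary least-squares fit (independent of the
# package's Gram-matrix route).
ols_multiple_correlation <- function(x, y) {
  sqrt(suppressWarnings(summary(lm(y ~ x))$r.squared))
}

# Exhaustive best subset of size k through the OLS oracle.
brute_force_best_subset <- function(x, y, k) {
  combos <- combn(ncol(x), k)
  r <- apply(combos, 2, function(ix) {
    ols_multiple_correlation(x[, ix, drop = FALSE], y)
  })
  best <- which.max(r)  # first maximum = lexicographically smallest set
  list(subset = combos[, best], corr = r[best])
}

# Generic LP oracle: scipy.optimize.linprog (HiGHS) through the python on
# PATH. Solves min c'z s.t. A z >= b, z >= 0 and returns the objective.
scipy_lp_objective <- function(A, b, cc) {
  dir <- tempfile("lp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  inp <- file.path(dir, "problem.json")
  out <- file.path(dir, "solution.json")
  writeLines(jsonlite::toJSON(list(A = A, b = b, c = cc), digits = NA), inp)
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("p = json.load(open(%s))", deparse(inp)),
    "A = np.array(p['A'], float); b = np.array(p['b'], float)",
    "c = np.array(p['c'], float)",
    "r = linprog(c, A_ub=-A, b_ub=-b, bounds=[(0, None)] * A.shape[1],",
    "            method='highs')",
    sprintf("json.dump({'objective': r.fun, 'status': int(r.status)}, open(%s, 'w'))",
            deparse(out))
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  res <- jsonlite::read_json(out)
  stopifnot(res$status == 0)
  res$objective
}

# LP oracle applied directly to an L1-SVM instance (same formulation the
# package uses, solved by the external solver).
scipy_svm_objective <- function(x, y01, penalties) {
  n <- nrow(x); p <- ncol(x)
  ys <- ifelse(y01 == 1, 1, -1)
  A <- cbind(x * ys, -x * ys, ys, -ys, diag(n))
  cc <- c(rep(1, 2 * p), 0, 0,
          ifelse(ys > 0, penalties[["pos"]], penalties[["neg"]]))
  scipy_lp_objective(A, rep(1, n), cc)
}

# A deterministic suppressor instance: x1 is the best single feature but the
# pair {x2, x3} reconstructs the outcome exactly (x2 - x3 = y), so the
# exhaustive size-2 search drops x1.
suppressor_instance <- function(n = 60, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  u <- rnorm(n)
  x <- cbind(x1 = y + rnorm(n, sd = 0.4),
             x2 = u,
             x3 = u - y,
             x4 = rnorm(n))
  list(x = x, y = y)
}

# Nested-optima instance: orthogonal features with strictly decreasing
# signal, so best subsets are nested and greedy = exhaustive.
nested_instance <- function(n = 80, p = 4, seed = 9) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- sapply(seq_len(p), function(j) y * (1.5 - 0.25 * j) + rnorm(n))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# Small planted cohort feature set used by SVM/ensemble tests.
planted_features <- function(seed = 1, dropout = 0) {
  cohort_features(sample_cohort(cohort_config(dropout_prob = dropout,
                                              seed = seed)))
}

panel_trio <- c("Ang-2", "Ang-1", "HCO3")
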