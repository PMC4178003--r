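test_that("configuration invariants are validated", {
  expect_error(cohort_config(severe_fraction = 0), "strictly between")
  expect_error(cohort_config(severe_fraction = 1), "strictly between")
  expect_error(cohort_config(n_patients = 1), "at least 2")
  expect_error(cohort_config(electrolyte_block_rho = c(1.5, 0.3)), "\\[-1, 1\\]")
  expect_error(cohort_config(ang_pair_rho = 0.5), "two values")
  expect_error(cohort_config(dropout_prob = 1), "dropout_prob")
  expect_error(cohort_config(effect_sizes = c(Bogus = 1)), "unknown variables")
  # a 4-variable equicorrelated block with rho < -1/3 is not PSD
  expect_error(cohort_config(electrolyte_block_rho = c(-0.9, 0.3)),
               "positive semi-definite")
})

test_that("identical seeds give identical cohorts", {
  cfg <- cohort_config()
  expect_identical(sample_cohort(cfg, seed = 42), sample_cohort(cfg, seed = 42))
  expect_false(identical(sample_cohort(cfg, seed = 42),
                         sample_cohort(cfg, seed = 43)))
})

test_that("cohort structure follows the sampling schedule", {
  co <- sample_cohort(cohort_config(n_patients = 45, seed = 2))
  expect_equal(length(unique(co$patient_id)), 45)
  sched <- data.frame(day = c(1, 1, 2, 2, 3, 3, 4:7), draw = 1:10)
  for (pid in unique(co$patient_id)) {
    sub <- co[co$patient_id == pid, ]
    expect_lte(nrow(sub), 10)
    expect_true(all(diff(sub$draw) > 0))          # strictly increasing draws
    expect_identical(sub$draw, seq_len(nrow(sub)))  # no gap after dropout
    expect_true(all(sub$day <= 7))
    expect_true(all(table(sub$day[sub$day <= 3]) <= 2))
    expect_true(all(table(sub$day[sub$day >= 4]) <= 1))
    expect_equal(length(unique(sub$label)), 1)    # label constant per patient
    # schedule consistency: observed (day, draw) pairs prefix the template
    expect_equal(sub$day, sched$day[seq_len(nrow(sub))])
  }
  expect_equal(sum(co$label == 1) > 0, TRUE)
})

test_that("the ratio column is exactly Ang-2 / Ang-1", {
  co <- sample_cohort(cohort_config(seed = 6))
  expect_equal(co[["Ang-2/Ang-1"]], co[["Ang-2"]] / co[["Ang-1"]])
  expect_true(all(co[["Ang-1"]] > 0) && all(co[["Ang-2"]] > 0))
})

test_that("group sizes follow the severe fraction", {
  cfg <- cohort_config(n_patients = 45, severe_fraction = 0.4)
  co <- sample_cohort(cfg, seed = 3)
  per_patient <- unique(co[, c("patient_id", "label")])
  expect_equal(sum(per_patient$label), round(0.4 * 45))
})

test_that("planted correlation structure is recovered at large n", {
  for (s in 1:3) {
    co <- sample_cohort(cohort_config(n_patients = 400, dropout_prob = 0,
                                      seed = s))
    f <- cohort_features(co)
    g <- group_correlations(f$x, f$y)
    expect_gte(g[["0"]]["Na", "Cl"], 0.9)
    expect_gt(g[["1"]]["Ang-1", "Ang-2"], g[["0"]]["Ang-1", "Ang-2"])
    # configured block values on the latent (log) scale, before decay sets in
    early <- co$day <= 2
    la <- log(f$x[early, c("Ang-1", "Ang-2")])
    y2 <- f$y[early]
    expect_lt(abs(cor(la[y2 == 1, 1], la[y2 == 1, 2]) - 0.76), 0.1)
    expect_lt(abs(cor(la[y2 == 0, 1], la[y2 == 0, 2]) - 0.21), 0.1)
    expect_lt(abs(cor(f$x[early, "Na"][y2 == 0],
                      f$x[early, "Cl"][y2 == 0]) - 0.96), 0.1)
    # noise columns carry no label information
    expect_lte(abs(cor(f$x[, "g-Noise"], f$y)), 0.15)
    expect_lte(abs(cor(f$x[, "u-Noise"], f$y)), 0.15)
  }
})

test_that("attrition shortens follow-up monotonically", {
  co <- sample_cohort(cohort_config(dropout_prob = 0.3, seed = 8))
  counts <- table(factor(co$day, levels = 1:7))
  # day 1 has two scheduled draws for everyone; later days cannot have more
  # patients than earlier ones
  per_day_patients <- vapply(1:7, function(d) {
    length(unique(co$patient_id[co$day == d]))
  }, numeric(1))
  expect_true(all(diff(per_day_patients) <= 0))
})

test_that("cohort TSV round-trips and reports schema errors", {
  co <- sample_cohort(cohort_config(seed = 42))
  tf <- tempfile(fileext = ".tsv")
  write_cohort(co, tf)
  back <- read_cohort(tf)
  f1 <- cohort_features(co); f2 <- cohort_features(back)
  expect_lt(max(abs(f1$x - f2$x)), 1e-9)
  expect_identical(f1$y, f2$y)

  # hand-written 3-row file
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tday\tdraw\tAng-2\tlabel",
               "P1\t1\t1\t100\t0", "P1\t1\t2\t200\t0", "P2\t1\t1\t300\t1"), tf2)
  small <- read_cohort(tf2)
  expect_equal(nrow(small), 3)
  expect_equal(small[["Ang-2"]], c(100, 200, 300))

  # missing label column
  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tday\tdraw\tAng-2", "P1\t1\t1\t100"), tf3)
  expect_error(read_cohort(tf3), "label")

  # non-numeric biomarker cell names the row
  tf4 <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tday\tdraw\tAng-2\tlabel",
               "P1\t1\t1\t100\t0", "P1\t1\t2\toops\t0"), tf4)
  expect_error(read_cohort(tf4), "row 2")
})
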