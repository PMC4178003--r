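#' Default biomarker panel description
#'
#' Returns the table of the 19 variables carried by a cohort: the 17 clinical
#' variables (demographics, admission mortality score, blood counts,
#' electrolytes, renal markers, angiopoietins and their ratio, VEGF) plus two
#' synthetic noise channels used as irrelevant-feature controls. `mean` and
#' `sd` are the raw-unit location and scale of the *non-severe* group;
#' `effect` is the standardized shift of the severe group on the latent
#' (Gaussian) scale, so pooled two-group moments are wider than the
#' within-group ones. Strictly positive analytes (BUN, Cr, Ang-1, Ang-2,
#' VEGF) are modelled log-normally; the Ang-2/Ang-1 ratio is derived, never
#' drawn. Variables sharing a correlation block receive similar shifts, as
#' physiology would, so that no artificial within-block contrast outperforms
#' the markers themselves.
#'
#' Only the acute markers that treatment normalizes (Ang-2, Ang-1, HCO3;
#' `decays = TRUE`) are subject to the post-admission severity decay;
#' demographics, the admission mortality score, and the organ-dysfunction
#' mid-pack persist across the 7-day window.
#'
#' @return A data.frame with columns `name`, `dist` (one of `"normal"`,
#'   `"lognormal"`, `"ratio"`, `"gnoise"`, `"unoise"`), `mean`, `sd`,
#'   `effect`, `decays`.
#' @export
panel_variables <- function() {
  data.frame(
    name = c("Age", "Wgt", "PIM-2", "WBC", "Hgb", "Hct", "Plt", "Na", "K",
             "Cl", "HCO3", "BUN", "Cr", "Ang-1", "Ang-2", "Ang-2/Ang-1",
             "VEGF", "g-Noise", "u-Noise"),
    dist = c("normal", "normal", "normal", "normal", "normal", "normal",
             "normal", "normal", "normal", "normal", "normal", "lognormal",
             "lognormal", "lognormal", "lognormal", "ratio", "lognormal",
             "gnoise", "unoise"),
    mean = c(6, 25, 5, 12, 11, 33, 250, 138, 4, 103, 27.270, 12, 0.5,
             3300, 5500, NA, 150, 0, 0.5),
    sd = c(4.5, 15, 4, 6, 2, 6, 120, 4, 0.7, 5, 20, 7, 0.3,
           2000, 2750, NA, 135, 1, NA),
    effect = c(-0.30, -0.25, 0.35, 0.30, -0.30, -0.35, -0.35, -0.30, -0.40,
               -0.35, -1.60, 0.35, 0.30, -0.60, 2.20, NA, 0.30, 0, 0),
    decays = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, NA, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

# Correlated latent blocks (indices into panel_variables()); the electrolyte
# and angiopoietin blocks have group-specific correlations, the rest are
# physiological couplings shared by both groups.
cohort_blocks <- function(config) {
  list(
    list(name = "age-weight", idx = c(1L, 2L), rho = c(0.65, 0.65)),
    list(name = "hemoglobin-hematocrit", idx = c(5L, 6L), rho = c(0.80, 0.80)),
    list(name = "electrolyte", idx = c(8L, 9L, 10L, 11L),
         rho = config$electrolyte_block_rho),
    list(name = "bun-creatinine", idx = c(12L, 13L), rho = c(0.45, 0.45)),
    list(name = "angiopoietin", idx = c(14L, 15L), rho = config$ang_pair_rho)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [sample_cohort()]. Defaults
#' emulate a 45-patient pediatric intensive-care sepsis cohort consolidated
#' into two severity groups, with a strong planted Ang-2 (up) / Ang-1 (down) /
#' HCO3 (down) severe-group signature, group-specific correlation structure
#' (a tight electrolyte block in the non-severe group that decouples under
#' severe sepsis; an angiopoietin pair that couples under severe sepsis), a
#' twice-daily-then-daily sampling schedule capped at 10 draws over 7 days,
#' geometric attrition, and severe-group effects that decay geometrically
#' after `severity_decay_day` (treatment response).
#'
#' @param n_patients Number of patients (default 45).
#' @param severe_fraction Fraction of patients in the severe group, in (0,1).
#' @param variables Variable table as from [panel_variables()].
#' @param electrolyte_block_rho Length-2 numeric: equicorrelation of the
#'   Na/K/Cl/HCO3 block in the (non-severe, severe) groups.
#' @param ang_pair_rho Length-2 numeric: Ang-1/Ang-2 latent correlation in the
#'   (non-severe, severe) groups.
#' @param effect_sizes Optional named numeric vector of standardized
#'   severe-group shifts overriding the `effect` column of `variables`.
#' @param severity_decay_day Day after which the severe-group shifts of the
#'   decaying (acute) variables shrink by a factor 0.5 per day (default 2).
#' @param dropout_prob Per-draw probability that a patient is discharged after
#'   the draw (no later samples).
#' @param seed Integer RNG seed stored in the configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 45L,
                          severe_fraction = 0.4,
                          variables = panel_variables(),
                          electrolyte_block_rho = c(0.96, 0.30),
                          ang_pair_rho = c(0.21, 0.76),
                          effect_sizes = NULL,
                          severity_decay_day = 2L,
                          dropout_prob = 0.08,
                          seed = 1L) {
  if (!is.numeric(severe_fraction) || severe_fraction <= 0 || severe_fraction >= 1) {
    stop_fmt("severe_fraction must be strictly between 0 and 1")
  }
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop_fmt("n_patients must be at least 2")
  }
  n_severe <- round(severe_fraction * n_patients)
  n_severe <- max(1L, min(n_patients - 1L, as.integer(n_severe)))
  if (nrow(variables) != 19L) {
    stop_fmt("variables must describe exactly 19 columns, got %d", nrow(variables))
  }
  if (!identical(variables$dist[18:19], c("gnoise", "unoise"))) {
    stop_fmt("the last two variables must be the noise columns")
  }
  if (!is.null(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), variables$name)
    if (length(bad)) stop_fmt("unknown variables in effect_sizes: %s",
                              paste(bad, collapse = ", "))
    variables$effect[match(names(effect_sizes), variables$name)] <- effect_sizes
  }
  for (rho in list(electrolyte_block_rho = electrolyte_block_rho,
                   ang_pair_rho = ang_pair_rho)) {
    if (length(rho) != 2L || any(!is.finite(rho)) || any(abs(rho) > 1)) {
      stop_fmt("block correlations must be two values in [-1, 1]")
    }
  }
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop_fmt("dropout_prob must be in [0, 1)")
  }
  cfg <- structure(list(
    n_patients = n_patients,
    n_severe = n_severe,
    severe_fraction = severe_fraction,
    variables = variables,
    electrolyte_block_rho = as.numeric(electrolyte_block_rho),
    ang_pair_rho = as.numeric(ang_pair_rho),
    severity_decay_day = as.integer(severity_decay_day),
    dropout_prob = dropout_prob,
    seed = as.integer(seed)
  ), class = "cohort_config")
  # validate implied covariance blocks up front
  for (g in 1:2) {
    for (bl in cohort_blocks(cfg)) {
      m <- length(bl$idx)
      S <- matrix(bl$rho[g], m, m); diag(S) <- 1
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        stop_fmt("correlation block '%s' is not positive semi-definite (group %d)",
                 bl$name, g)
      }
    }
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: %d patients (%d severe), seed %d\n",
              x$n_patients, x$n_severe, x$seed))
  cat(sprintf("  electrolyte block rho: %.2f / %.2f (non-severe / severe)\n",
              x$electrolyte_block_rho[1], x$electrolyte_block_rho[2]))
  cat(sprintf("  Ang-1/Ang-2 rho:       %.2f / %.2f\n",
              x$ang_pair_rho[1], x$ang_pair_rho[2]))
  cat(sprintf("  severity decay after day %d, dropout %.2f/draw\n",
              x$severity_decay_day, x$dropout_prob))
  invisible(x)
}

# Sampling schedule: two draws/day on days 1-3, one on days 4-7 (max 10).
draw_schedule <- function() {
  data.frame(day = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L, 7L),
             draw = 1:10)
}

# Cholesky factor of the latent correlation matrix for one group.
latent_chol <- function(config, group) {
  p <- nrow(config$variables)
  S <- diag(p)
  for (bl in cohort_blocks(config)) {
    S[bl$idx, bl$idx] <- bl$rho[group + 1L]
    diag(S)[bl$idx] <- 1
  }
  chol(S)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws one latent Gaussian vector per (patient, draw) with group-specific
#' mean shifts and block correlations, maps it to raw units (log-normal for
#' strictly positive analytes), derives the Ang-2/Ang-1 ratio, appends
#' independent Gaussian and uniform noise columns, and applies the sampling
#' schedule with geometric attrition. Severe-group shifts of variables with
#' `decays = TRUE` are multiplied by `0.5^(day - severity_decay_day)` after
#' the decay day; other shifts persist through the week.
#'
#' @param config A [cohort_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return A data.frame of class `sepsis_cohort` with columns `patient_id`,
#'   `day`, `draw`, the 19 variables, and `label` (1 = severe).
#' @export
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  vars <- config$variables
  p <- nrow(vars)
  sched <- draw_schedule()
  with_seed(seed, {
    severe <- rep(0L, config$n_patients)
    severe[sample.int(config$n_patients, config$n_severe)] <- 1L
    chol_by_group <- list(latent_chol(config, 0L), latent_chol(config, 1L))
    rows <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      g <- severe[i]
      n_draws <- nrow(sched)
      if (config$dropout_prob > 0) {
        gone <- which(rbinom(n_draws, 1L, config$dropout_prob) == 1L)
        if (length(gone)) n_draws <- min(n_draws, gone[1])
      }
      sub <- sched[seq_len(n_draws), , drop = FALSE]
      Z <- matrix(rnorm(n_draws * p), n_draws, p) %*% chol_by_group[[g + 1L]]
      decay <- ifelse(sub$day <= config$severity_decay_day, 1,
                      0.5 ^ (sub$day - config$severity_decay_day))
      V <- matrix(0, n_draws, p)
      for (j in seq_len(p)) {
        eff <- vars$effect[j]
        shift <- if (g == 1L && !is.na(eff)) {
          if (isTRUE(vars$decays[j])) eff * decay else eff
        } else 0
        zj <- Z[, j] + shift
        V[, j] <- switch(vars$dist[j],
          normal = vars$mean[j] + vars$sd[j] * zj,
          lognormal = {
            s2 <- log(1 + (vars$sd[j] / vars$mean[j])^2)
            exp(log(vars$mean[j]) - s2 / 2 + sqrt(s2) * zj)
          },
          gnoise = rnorm(n_draws),
          unoise = runif(n_draws),
          ratio = NA_real_)
      }
      ratio_col <- which(vars$dist == "ratio")
      if (length(ratio_col)) {
        V[, ratio_col] <- V[, vars$name == "Ang-2"] / V[, vars$name == "Ang-1"]
      }
      df <- data.frame(patient_id = sprintf("P%03d", i),
                       day = sub$day, draw = sub$draw,
                       stringsAsFactors = FALSE)
      vals <- as.data.frame(V)
      names(vals) <- vars$name
      df <- cbind(df, vals, label = g)
      rows[[i]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "config_seed") <- as.integer(seed)
    class(out) <- c("sepsis_cohort", "data.frame")
    out
  })
}

#' Extract the feature matrix and labels from a cohort
#'
#' @param cohort A cohort data.frame as from [sample_cohort()] or
#'   [read_cohort()].
#' @return A list with `x` (numeric matrix, one column per variable), `y`
#'   (0/1 integer labels) and `keys` (patient/day/draw data.frame).
#' @export
cohort_features <- function(cohort) {
  req <- c("patient_id", "day", "draw", "label")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop_fmt("cohort lacks required columns: %s",
                             paste(miss, collapse = ", "))
  feats <- setdiff(names(cohort), req)
  x <- as.matrix(cohort[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as_binary_label(cohort$label),
       keys = cohort[, c("patient_id", "day", "draw")])
}

#' Write a cohort to a tab-separated file
#'
#' @param cohort Cohort data.frame.
#' @param path Output path; the header row carries the column names verbatim.
#' @export
write_cohort <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a cohort from a tab-separated file
#'
#' @param path Path to a TSV with columns `patient_id`, `day`, `draw`, the
#'   biomarker variables, and `label`.
#' @return A `sepsis_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_fmt("cohort file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("patient_id", "day", "draw", "label")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_fmt("cohort file %s lacks required columns: %s", path,
             paste(miss, collapse = ", "))
  }
  feats <- setdiff(names(df), req)
  for (f in c(feats, "day", "draw", "label")) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        stop_fmt("non-numeric value in column '%s' at data row %d", f,
                 which(is.na(num))[1])
      }
      df[[f]] <- num
    }
  }
  if (anyNA(df[feats])) stop_fmt("cohort file %s contains missing values", path)
  class(df) <- c("sepsis_cohort", "data.frame")
  df
}
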