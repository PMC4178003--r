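#' Configuration for the end-to-end pipeline
#'
#' Bundles the generator settings and analysis parameters consumed by
#' [run_pipeline()]. Defaults run the full synthetic study at a reduced
#' scale suitable for interactive use.
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when `cohort_file` points at an existing cohort TSV).
#' @param cohort_file Optional path to a cohort TSV to analyze instead of
#'   generating one.
#' @param method Selection method for the panel-size curve: `"cca"`
#'   (exhaustive stepwise trace) or `"fs"` (greedy forward selection).
#' @param k_max Largest panel size traced and evaluated.
#' @param B,R Ensemble size and number of repeated splits per evaluation.
#' @param n_trees Random-forest size for the importance ranking.
#' @param seed Master seed.
#' @param normalization `"global"` or `"train-only"` (see
#'   [repeated_evaluation()]).
#' @param out_dir Output directory for the report bundle.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cohort_file = NULL,
                            method = c("cca", "fs"),
                            k_max = 19L, B = 20L, R = 25L,
                            n_trees = 1000L, seed = 42L,
                            normalization = "global",
                            out_dir = tempfile("sepsipanel_run_")) {
  method <- match.arg(method)
  stopifnot(k_max >= 1L, B >= 1L, R >= 1L, n_trees >= 1L)
  structure(list(cohort = cohort, cohort_file = cohort_file, method = method,
                 k_max = as.integer(k_max), B = as.integer(B),
                 R = as.integer(R), n_trees = as.integer(n_trees),
                 seed = as.integer(seed), normalization = normalization,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# provenance header written at the top of every report file
pipeline_header <- function(config) {
  cfg_str <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  c(sprintf("# seed=%d", config$seed),
    sprintf("# config_md5=%s", md5_string(cfg_str)))
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline report table
#'
#' @param path A TSV written by [run_pipeline()] (provenance header lines
#'   start with `#`).
#' @return A data.frame; the header lines are attached as attribute
#'   `"provenance"`.
#' @export
read_report_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.delim(text = lines[!startsWith(lines, "#")], check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "provenance") <- hdr
  df
}

#' Run the full biomarker-panel pipeline
#'
#' Generates (or loads) a cohort, then runs every stage of the analysis:
#' group-wise correlation matrices, the stepwise best-subset trace and greedy
#' forward selection, measure-versus-panel-size curves for the CCA and
#' random-forest rankings, single-biomarker evaluation, a fitted sparse SVM
#' on the size-3 panel, the OOB permutation importance ranking, and severity
#' trajectories under the published score. Each stage writes a TSV (or JSON
#' for the model) into `config$out_dir` with a seed/config-hash provenance
#' header; a failing stage aborts with the stage name while earlier outputs
#' are preserved.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of output paths plus the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- pipeline_header(config)
  paths <- list()
  results <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s]", name)
    tryCatch(expr, error = function(e) {
      stop_fmt("pipeline stage '%s' failed: %s (partial outputs in %s)",
               name, conditionMessage(e), config$out_dir)
    })
  }

  cohort <- stage("cohort", {
    ch <- if (!is.null(config$cohort_file)) read_cohort(config$cohort_file)
          else sample_cohort(config$cohort, seed = config$seed)
    paths$cohort <- file.path(config$out_dir, "cohort.tsv")
    write_report_tsv(as.data.frame(ch), paths$cohort, hdr)
    ch
  })
  feats <- cohort_features(cohort)

  stage("correlations", {
    gc <- group_correlations(feats$x, feats$y)
    for (g in names(gc)) {
      p <- file.path(config$out_dir, sprintf("correlations_group%s.tsv", g))
      paths[[paste0("correlations_group", g)]] <- p
      write_report_tsv(data.frame(feature = rownames(gc[[g]]),
                                  as.data.frame(gc[[g]], check.names = FALSE),
                                  check.names = FALSE),
                       p, hdr)
    }
    results$correlations <- gc
  })

  trace <- stage("selection", {
    tr <- stepwise_trace(feats$x, feats$y, k_max = config$k_max)
    paths$selection_trace <- file.path(config$out_dir, "selection_trace.tsv")
    write_report_tsv(as.data.frame(tr), paths$selection_trace, hdr)
    fs <- forward_selection(feats$x, feats$y, k_max = config$k_max)
    paths$forward_selection <- file.path(config$out_dir, "forward_selection.tsv")
    write_report_tsv(fs, paths$forward_selection, hdr)
    results$forward_selection <- fs
    tr
  })
  results$trace <- trace

  forest <- stage("importance", {
    fo <- panel_forest(feats$x, feats$y, n_trees = config$n_trees,
                       seed = config$seed)
    imp <- mda_importance(fo)
    paths$importance <- file.path(config$out_dir, "importance.tsv")
    write_report_tsv(as.data.frame(imp), paths$importance, hdr)
    results$importance <- imp
    fo
  })

  stage("curves", {
    ranking <- if (config$method == "cca") trace else results$forward_selection
    cv <- subset_size_curve(feats$x, feats$y, ranking, B = config$B,
                            R = config$R, seed = config$seed,
                            k_max = config$k_max,
                            normalization = config$normalization)
    paths$curve_selected <- file.path(config$out_dir,
                                       sprintf("curve_%s.tsv", config$method))
    write_report_tsv(cv, paths$curve_selected, hdr)
    rf_rank <- results$importance$feature
    cv_rf <- subset_size_curve(feats$x, feats$y, rf_rank, B = config$B,
                               R = config$R, seed = config$seed,
                               k_max = config$k_max,
                               normalization = config$normalization)
    paths$curve_rf <- file.path(config$out_dir, "curve_rf.tsv")
    write_report_tsv(cv_rf, paths$curve_rf, hdr)
    results$curve <- cv
  })

  stage("singles", {
    singles <- do.call(rbind, lapply(colnames(feats$x), function(nm) {
      ev <- repeated_evaluation(feats$x, feats$y, subset = nm, B = config$B,
                                R = config$R, seed = config$seed,
                                normalization = config$normalization)
      data.frame(variable = nm, measure = ev$measure, mean = ev$mean,
                 se = ev$se, stringsAsFactors = FALSE)
    }))
    paths$singles <- file.path(config$out_dir, "single_biomarkers.tsv")
    write_report_tsv(singles, paths$singles, hdr)
    results$singles <- singles
  })

  stage("model", {
    panel <- trace_members(trace, min(3L, config$k_max))
    fit <- l1svm(feats$x[, panel, drop = FALSE], feats$y)
    paths$model <- file.path(config$out_dir, "model.json")
    write_l1svm(fit, paths$model)
    results$model <- fit
  })

  stage("trajectory", {
    traj <- score_cohort(cohort)
    paths$trajectory <- file.path(config$out_dir, "trajectory.tsv")
    write_report_tsv(traj$samples, paths$trajectory, hdr)
    paths$trajectory_groups <- file.path(config$out_dir, "trajectory_groups.tsv")
    write_report_tsv(traj$by_group, paths$trajectory_groups, hdr)
    results$trajectory <- traj
  })

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(hdr,
               sprintf("method=%s k_max=%d B=%d R=%d n_trees=%d", config$method,
                       config$k_max, config$B, config$R, config$n_trees),
               sprintf("outputs=%s", paste(basename(unlist(paths)),
                                           collapse = ","))),
             log_path)
  paths$run_log <- log_path
  invisible(list(paths = paths, results = results, config = config))
}
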