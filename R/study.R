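#' Configuration of an in-silico study
#'
#' Bundles everything needed to rerun the full experiment on the virtual
#' platform: the number of trials per condition (16 in the published design),
#' trial seeds, arena/kinematics/fish parameter blocks, and the
#' transfer-entropy settings.
#'
#' @param n_trials Trials per condition (>= 2).
#' @param base_seed Integer; trial seeds are derived deterministically from
#'   it (one distinct seed per condition x trial).
#' @param arena,kinematics,fish Parameter objects; see [arena_geometry()],
#'   [robot_kinematics()], [fish_params()].
#' @param habituation_s,observation_s Trial phase durations, seconds.
#' @param te_axes Axes on which to run the transfer-entropy analysis.
#' @param n_perm Surrogate permutations for the significance test.
#' @param conditions Conditions to simulate.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_trials = 16, base_seed = 1,
                         arena = arena_geometry(),
                         kinematics = robot_kinematics(),
                         fish = fish_params(),
                         habituation_s = 600, observation_s = 360,
                         te_axes = c("depth", "length"), n_perm = 1000,
                         conditions = c("control", "open_loop",
                                        "closed_loop")) {
  stopifnot(n_trials >= 2, observation_s %% 120 == 0)
  structure(as.list(environment()), class = "study_config")
}

#' Run the full in-silico study
#'
#' Simulates `n_trials` trials per condition, computes the per-trial,
#' per-2-min-bin metric table, runs the transfer-entropy surrogate test per
#' condition and axis (robot conditions only), and summarizes metrics as mean
#' +/- standard error per condition x bin. Fully deterministic given
#' `base_seed`. Optionally writes all outputs (trial directories, tidy
#' metrics CSV, TE JSON, summary CSV) under `out_dir`.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `study_report` with `metrics` (tidy data frame),
#'   `summary` (per-condition per-bin means and SEMs), `te` (nested list of
#'   `surrogate_test` objects by condition and axis), and `trials` (list of
#'   trial records).
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  conds <- config$conditions
  trials <- list()
  metrics <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    for (k in seq_len(config$n_trials)) {
      seed <- config$base_seed * 10000L + ci * 1000L + k
      tr <- run_trial(cond, seed = seed,
                      kinematics = config$kinematics, fish = config$fish,
                      arena = config$arena,
                      habituation_s = config$habituation_s,
                      observation_s = config$observation_s)
      id <- sprintf("%s_%02d", cond, k)
      trials[[id]] <- tr
      metrics[[id]] <- trial_metrics(tr, trial_id = id)
      if (!is.null(out_dir))
        write_trial(tr, file.path(out_dir, "trials", id))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  te <- list()
  for (cond in setdiff(conds, "control")) {
    ids <- grep(paste0("^", cond, "_"), names(trials), value = TRUE)
    te[[cond]] <- list()
    for (axis in config$te_axes) {
      series <- lapply(trials[ids], trial_te_series, axis = axis)
      set.seed(config$base_seed * 100L + match(axis, c("depth", "length")))
      te[[cond]][[axis]] <- surrogate_test(
        lapply(series, `[[`, "fish"),
        lapply(series, `[[`, "robot"),
        n_perm = config$n_perm)
    }
  }

  summary <- summarize_metrics(metrics)
  report <- structure(list(metrics = metrics, summary = summary,
                           te = te, trials = trials, config = config),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    te_json <- lapply(te, function(ax) lapply(ax, function(s)
      list(observed_mean_te = s$observed_mean_te,
           per_trial_te = s$per_trial_te,
           q05 = s$q05, q95 = s$q95, significant = s$significant)))
    jsonlite::write_json(te_json, file.path(out_dir, "te.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Per-condition, per-bin summary (mean and standard error)
#'
#' @param metrics Tidy metric table from [trial_metrics()] rows.
#' @return Data frame with one row per condition x time bin x metric, columns
#'   `mean` and `sem` (`sd / sqrt(n)`; `NA` when fewer than 2 trials).
#' @export
summarize_metrics <- function(metrics) {
  vars <- setdiff(names(metrics), c("trial_id", "condition", "time_bin"))
  groups <- split(seq_len(nrow(metrics)),
                  list(condition = metrics$condition,
                       time_bin = metrics$time_bin), drop = TRUE)
  out <- lapply(vars, function(v) {
    cells <- lapply(groups, function(ix) {
      x <- metrics[[v]][ix]
      x <- x[!is.na(x)]
      data.frame(condition = metrics$condition[ix[1]],
                 time_bin = metrics$time_bin[ix[1]], metric = v,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sem = if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                       else NA_real_,
                 n = length(x), stringsAsFactors = FALSE)
    })
    do.call(rbind, cells)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("In-silico study: %d trials x %d condition(s)\n",
              x$config$n_trials, length(x$config$conditions)))
  for (cond in names(x$te)) for (axis in names(x$te[[cond]])) {
    s <- x$te[[cond]][[axis]]
    cat(sprintf("  TE %s / %s axis: %.4f bits (null q95 %.4f) %s\n",
                cond, axis, s$observed_mean_te, s$q95,
                if (s$significant) "*" else ""))
  }
  invisible(x)
}
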