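#' Simulate a cohort and write it to disk
#'
#' End-to-end simulation stage: generates a synthetic cohort, writes one
#' track CSV per subject plus a manifest mirroring the subject-table
#' columns with the ground truths (`kappa`, `target_ci`) appended, and a
#' run log recording the seed, a configuration hash and counts. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param config An [assay_config()].
#' @param ... Passed to [generate_cohort()].
#' @return The manifest tibble, invisibly; files are written under
#'   `out_dir` (`manifest.csv`, `tracks/<subject_id>.csv`, `run_log.txt`).
#' @export
run_simulate <- function(out_dir, seed = 1, config = assay_config(), ...) {
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(..., config = config, seed = seed)
  manifest <- cohort$subjects
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  for (id in manifest$subject_id) {
    tr <- cohort$tracks[cohort$tracks$subject_id == id, , drop = FALSE]
    write_tracks(tr[, setdiff(names(tr), "subject_id")],
                 file.path(out_dir, "tracks", paste0(id, ".csv")),
                 gradient_axis = config$gradient_axis)
  }
  cfg_hash <- rlang::hash(config)
  writeLines(c(
    sprintf("seed: %d", as.integer(seed)),
    sprintf("config_hash: %s", cfg_hash),
    sprintf("n_subjects: %d", nrow(manifest)),
    sprintf("n_tracks: %d", length(unique(paste(cohort$tracks$subject_id,
                                                cohort$tracks$track_id))))
  ), file.path(out_dir, "run_log.txt"))
  invisible(manifest)
}

#' Analyze track files (or a track tibble) into migration metrics
#'
#' Analysis stage: reads the track CSV dialect (or takes a tibble), then
#' computes per-track chemotactic index and speed and the per-condition
#' mean ± SEM summary. When `out_dir` is given, writes
#' `per_track_metrics.tsv` and `condition_summary.tsv`.
#'
#' @param tracks A track tibble, one path, or a character vector of paths.
#' @param gradient_axis Unit vector; defaults to the axis stored in the
#'   file header (or `c(0, -1)` for tibble input).
#' @param out_dir Optional output directory.
#' @return A list with `per_track` and `summary` tibbles.
#' @export
run_analyze <- function(tracks, gradient_axis = NULL, out_dir = NULL) {
  if (is.character(tracks)) {
    parts <- map(tracks, read_tracks)
    if (is.null(gradient_axis)) gradient_axis <- attr(parts[[1]], "gradient_axis")
    nm <- sub("\\.csv$", "", basename(tracks))
    tracks <- map_dfr(seq_along(parts), function(i) {
      tibble(subject_id = nm[i], parts[[i]])
    })
  }
  gradient_axis <- gradient_axis %||% c(0, -1)
  per_track <- track_metrics(tracks, gradient_axis)
  smry <- summarize_conditions(tracks, gradient_axis)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(per_track, file.path(out_dir, "per_track_metrics.tsv"),
                     progress = FALSE)
    readr::write_tsv(smry, file.path(out_dir, "condition_summary.tsv"),
                     progress = FALSE)
  }
  list(per_track = per_track, summary = smry)
}

#' Cohort statistics report
#'
#' Statistics stage: given a subject table (path or tibble), runs the
#' COPD-vs-control pooled t test on per-subject C.I. and speed, the
#' C.I.–FEV1/FVC regression on all COPD subjects, the leave-one-out scan,
#' and the C.I.–speed correlation. When `out_dir` is given, writes
#' `group_tests.tsv`, `loo_scan.tsv` and a human-readable `report.txt`.
#'
#' @param subjects A subject-table tibble or a CSV path
#'   ([read_subject_table()] dialect).
#' @param out_dir Optional output directory.
#' @return A list: `t_ci`, `t_speed` (t-test tibbles), `regression_all`
#'   (`spiro_fit`), `loo` (scan tibble), `ci_speed` (OLS tibble).
#' @export
#' @examples
#' rep <- run_stats(read_subject_table())
#' rep$t_ci$p_value
run_stats <- function(subjects, out_dir = NULL) {
  if (is.character(subjects)) subjects <- read_subject_table(subjects)
  t_ci <- two_sample_ttest(subjects, ci_mean, group)
  t_speed <- two_sample_ttest(subjects, speed_mean_um_s, group)
  reg_all <- regress_ci_on_spirometry(subjects)
  loo <- leave_one_out_scan(subjects)
  ci_speed <- correlate_ci_speed(subjects)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(bind_rows(
      tibble(outcome = "ci_mean", t_ci),
      tibble(outcome = "speed_mean_um_s", t_speed)
    ), file.path(out_dir, "group_tests.tsv"), progress = FALSE)
    readr::write_tsv(loo, file.path(out_dir, "loo_scan.tsv"), progress = FALSE)
    best <- attr(loo, "best_fit")
    writeLines(c(
      "Cohort chemotaxis statistics",
      sprintf("COPD vs control C.I.: t = %.3f, df = %g, p = %.4g%s",
              t_ci$statistic, t_ci$df, t_ci$p_value,
              if (t_ci$significant) " (*)" else ""),
      sprintf("COPD vs control speed: t = %.3f, df = %g, p = %.4g%s",
              t_speed$statistic, t_speed$df, t_speed$p_value,
              if (t_speed$significant) " (*)" else ""),
      sprintf("C.I. ~ FEV1/FVC (all COPD): slope = %.5f, r^2 = %.4f",
              reg_all$summary$slope, reg_all$summary$r_squared),
      sprintf("Leave-one-out best: exclude %s -> slope = %.5f, r^2 = %.4f",
              loo$excluded_id[1], best$summary$slope, best$summary$r_squared),
      sprintf("C.I. ~ speed: r^2 = %.4f", ci_speed$r_squared)
    ), file.path(out_dir, "report.txt"))
  }
  list(t_ci = t_ci, t_speed = t_speed, regression_all = reg_all,
       loo = loo, ci_speed = ci_speed)
}
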