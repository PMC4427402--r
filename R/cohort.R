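#' Generate a synthetic COPD / control cohort
#'
#' Builds a ground-truthed cohort with the statistical structure the
#' downstream analyses assume: sputum from COPD-like subjects is more potent
#' (higher target chemotactic index) than control sputum, and within the
#' COPD group the target C.I. decreases linearly with FEV1/FVC (worse
#' obstruction, stronger chemotaxis) up to Gaussian noise. Each subject's
#' directional concentration is obtained with [calibrate_kappa()] from the
#' target C.I., and `tracks_per_subject` biased walks are simulated per
#' subject. Migration speed is drawn independently of the C.I. (no
#' C.I.–speed correlation, matching the measured cohort).
#'
#' Defaults are the group means/SDs of the packaged subject table
#' (COPD C.I. 0.39 ± 0.097, control 0.22 ± 0.062; speeds 0.158 and
#' 0.221 µm/s) and its FEV1/FVC range (35–75).
#'
#' @param n_copd,n_control Subjects per group (each >= 2).
#' @param ci_copd_mean,ci_copd_sd,ci_control_mean,ci_control_sd Target
#'   C.I. distribution per group; means must be in `[0, 1)`.
#' @param speed_copd_mean,speed_control_mean,speed_sd Per-subject mean step
#'   speed law (µm/s).
#' @param fev1fvc_range Range (×100%) the COPD subjects' FEV1/FVC is drawn
#'   from, uniformly.
#' @param correlation_noise_sd SD of the Gaussian noise on the C.I.–FEV1/FVC
#'   linear map. Default 0.03.
#' @param tracks_per_subject Tracks simulated per subject (>= 50 mirrors the
#'   "at least 50 cells per experiment" scoring rule). Default 50.
#' @param config An [assay_config()] shared by all subjects.
#' @param seed Root seed; all per-subject streams are derived from it, so
#'   the cohort is byte-reproducible.
#' @return A list of class `synthetic_cohort`: `subjects` (tibble with
#'   `subject_id`, `group`, `age`, `sex`, `fev1_fvc_pct`, `target_ci`,
#'   `kappa` (= ground-truth potency), `target_speed_um_s`) and `tracks`
#'   (track tibble with a `subject_id` column).
#' @export
#' @examples
#' coh <- generate_cohort(n_copd = 2, n_control = 2, tracks_per_subject = 5,
#'                        seed = 1)
#' coh$subjects
generate_cohort <- function(n_copd = 5, n_control = 5,
                            ci_copd_mean = 0.39, ci_copd_sd = 0.097,
                            ci_control_mean = 0.22, ci_control_sd = 0.062,
                            speed_copd_mean = 0.158, speed_control_mean = 0.221,
                            speed_sd = 0.05,
                            fev1fvc_range = c(35, 75),
                            correlation_noise_sd = 0.03,
                            tracks_per_subject = 50,
                            config = assay_config(), seed = 1) {
  if (n_copd < 2 || n_control < 2) abort("Each group needs at least 2 subjects.")
  for (m in c(ci_copd_mean, ci_control_mean)) {
    if (m < 0 || m >= 1) abort("Group C.I. means must be in [0, 1).")
  }
  if (tracks_per_subject < 1) abort("`tracks_per_subject` must be >= 1.")
  lo <- fev1fvc_range[1]; hi <- fev1fvc_range[2]
  if (!(hi > lo)) abort("`fev1fvc_range` must be increasing.")
  # slope chosen so a uniform FEV1/FVC induces SD = ci_copd_sd in the C.I.
  slope <- -ci_copd_sd * sqrt(12) / (hi - lo)

  subjects <- with_seed_if(derive_seed(seed, 0), {
    fev <- stats::runif(n_copd, lo, hi)
    ci_copd <- ci_copd_mean + slope * (fev - (lo + hi) / 2) +
      stats::rnorm(n_copd, 0, correlation_noise_sd)
    ci_ctrl <- stats::rnorm(n_control, ci_control_mean, ci_control_sd)
    sp <- c(stats::rnorm(n_copd, speed_copd_mean, speed_sd),
            stats::rnorm(n_control, speed_control_mean, speed_sd))
    tibble(
      subject_id = c(sprintf("COPD%02d", seq_len(n_copd)),
                     sprintf("CTRL%02d", seq_len(n_control))),
      group = rep(c("COPD", "control"), c(n_copd, n_control)),
      age = round(stats::runif(n_copd + n_control, 40, 80)),
      sex = sample(c("F", "M"), n_copd + n_control, replace = TRUE),
      fev1_fvc_pct = c(fev, rep(NA_real_, n_control)),
      target_ci = pmin(pmax(c(ci_copd, ci_ctrl), 0.01), 0.95),
      target_speed_um_s = pmin(pmax(sp, 0.02), 1)
    )
  })
  subjects$kappa <- vapply(subjects$target_ci, calibrate_kappa, 0)

  tracks <- map_dfr(seq_len(nrow(subjects)), function(i) {
    mot <- motility_params(kappa = subjects$kappa[i],
                           mean_step_speed = subjects$target_speed_um_s[i])
    tr <- simulate_tracks(tracks_per_subject, mot, config,
                          condition = subjects$group[i],
                          seed = derive_seed(seed, i))
    tibble(subject_id = subjects$subject_id[i], tr)
  })

  structure(list(subjects = subjects, tracks = tracks),
            class = "synthetic_cohort", seed = seed, config = config)
}

#' Measure a synthetic cohort with the track-metrics pipeline
#'
#' Runs [track_metrics()] per subject and aggregates to per-subject
#' mean ± SEM of C.I. and speed, yielding a table with the same columns the
#' measured subject table uses — ready for [two_sample_ttest()],
#' [regress_ci_on_spirometry()] and [leave_one_out_scan()].
#'
#' @param cohort A `synthetic_cohort`.
#' @return A tibble with one row per subject: `subject_id`, `group`, `age`,
#'   `sex`, `fev1_fvc_pct`, `ci_mean`, `ci_sem`, `speed_mean_um_s`,
#'   `speed_sem_um_s`, plus ground truths `target_ci` and `kappa`.
#' @export
measure_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  g <- attr(cohort, "config")$gradient_axis
  metrics <- track_metrics(cohort$tracks, g)
  per_subject <- metrics |>
    filter(!is.na(.data$ci)) |>
    group_by(subject_id) |>
    summarise(
      ci_mean = mean(.data$ci),
      ci_sem = stats::sd(.data$ci) / sqrt(dplyr::n()),
      speed_mean_um_s = mean(.data$speed_um_s),
      speed_sem_um_s = stats::sd(.data$speed_um_s) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  cohort$subjects |>
    left_join(per_subject, by = "subject_id") |>
    select(subject_id, group, age, sex, fev1_fvc_pct, ci_mean, ci_sem,
           speed_mean_um_s, speed_sem_um_s, target_ci, kappa)
}
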