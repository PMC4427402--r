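test_that("expected_ci matches the independent Bessel series oracle", {
  expect_identical(expected_ci(0), 0)
  expect_equal(expected_ci(Inf), 1)
  for (k in c(0.1, 0.5, 1, 2, 5, 10)) {
    expect_equal(expected_ci(k), bessel_ratio_series(k), tolerance = 1e-6)
  }
  # strictly increasing
  ks <- seq(0, 20, by = 0.5)
  expect_true(all(diff(expected_ci(ks)) > 0))
  expect_error(expected_ci(-1), ">= 0")
})

test_that("calibrate_kappa inverts expected_ci", {
  expect_identical(calibrate_kappa(0), 0)
  for (target in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(expected_ci(calibrate_kappa(target)), target, tolerance = 1e-6)
  }
  # first COPD subject's printed C.I.: brute-force bisection oracle
  target <- 0.533
  lo <- 0; hi <- 40
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (bessel_ratio_series(mid) < target) lo <- mid else hi <- mid
  }
  expect_equal(calibrate_kappa(0.533), (lo + hi) / 2, tolerance = 1e-5)
  expect_error(calibrate_kappa(1), "\\[0, 1\\)")
  expect_error(calibrate_kappa(-0.1), "\\[0, 1\\)")
})

test_that("von Mises sampler has the right mean resultant length", {
  withr::with_seed(7, {
    for (k in c(0, 1, 4)) {
      th <- rvonmises(20000, mu = 0.3, kappa = k)
      expect_true(all(th > -pi & th <= pi))
      r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
      expect_equal(r, expected_ci(k), tolerance = 0.02)
      expect_equal(atan2(mean(sin(th)), mean(cos(th))),
                   if (k == 0) atan2(mean(sin(th)), mean(cos(th))) else 0.3,
                   tolerance = 0.05)
    }
  })
})

cfg_wide <- assay_config(geometry = channel_geometry(width = 4000),
                         field_length = 4000, n_frames = 121)
centre_starts <- function(n) matrix(rep(2000, 2 * n), ncol = 2)

test_that("simulate_track honors its contracts", {
  # determinism from seed
  t1 <- simulate_track(motility_params(kappa = 2), cfg_wide, seed = 5)
  t2 <- simulate_track(motility_params(kappa = 2), cfg_wide, seed = 5)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), cfg_wide$n_frames)
  expect_equal(diff(t1$time_s), rep(cfg_wide$frame_interval, cfg_wide$n_frames - 1))
  # kappa = Inf, constant speed: straight line up-gradient, C.I. = 1
  ts <- simulate_track(motility_params(kappa = Inf, mean_step_speed = 0.2,
                                       speed_shape = Inf),
                       cfg_wide, start = c(2000, 2000), seed = 1)
  expect_equal(chemotactic_index(ts, cfg_wide$gradient_axis), 1, tolerance = 1e-12)
  expect_equal(migration_speed(ts), 0.2, tolerance = 1e-12)
  # start outside channel errors
  expect_error(simulate_track(motility_params(), cfg_wide, start = c(-5, 0)),
               "inside")
})

test_that("tracks never leave the channel (wall reflection)", {
  cfg_narrow <- assay_config(geometry = channel_geometry(width = 30),
                             field_length = 60, n_frames = 200)
  tr <- simulate_tracks(20, motility_params(kappa = 3, mean_step_speed = 0.5),
                        cfg_narrow, seed = 2)
  expect_true(all(tr$y_um >= 0 & tr$y_um <= 30))
  expect_true(all(tr$x_um >= 0 & tr$x_um <= 60))
})

test_that("mean C.I. over tracks converges to the calibrated target", {
  k <- calibrate_kappa(0.5)
  tr <- simulate_tracks(500, motility_params(kappa = k), cfg_wide,
                        start = centre_starts(500), seed = 11)
  m <- track_metrics(tr, cfg_wide$gradient_axis)
  expect_equal(mean(m$ci), 0.5, tolerance = 0.02)
  # deviation shrinks roughly as N^(-1/2): quarter the tracks, ~double the scatter
  devs <- vapply(1:8, function(s) {
    tr_s <- simulate_tracks(25, motility_params(kappa = k), cfg_wide,
                            start = centre_starts(25), seed = 100 + s)
    abs(mean(track_metrics(tr_s, cfg_wide$gradient_axis)$ci) - 0.5)
  }, 0)
  expect_gt(mean(devs), abs(mean(m$ci) - 0.5))
})

test_that("measured speed recovers the ground-truth mean in the wide channel", {
  tr <- simulate_tracks(300, motility_params(kappa = 1, mean_step_speed = 0.2),
                        cfg_wide, start = centre_starts(300), seed = 4)
  m <- track_metrics(tr, cfg_wide$gradient_axis)
  expect_equal(mean(m$speed_um_s), 0.2, tolerance = 0.004) # 2%
})

test_that("persistence keeps tracks valid and is reproducible", {
  mot <- motility_params(kappa = 1.5, persistence = 0.5)
  t1 <- simulate_tracks(5, mot, cfg_wide, seed = 9)
  t2 <- simulate_tracks(5, mot, cfg_wide, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 5 * cfg_wide$n_frames)
})

test_that("competing-gradient condition logic follows the dominance rules", {
  # terminal (fMLP-like) dominates intermediate regardless of potency
  cs <- condition_spec("fmlp_vs_il8",
                       top_attractant = attractant("fMLP", "terminal", 0.35),
                       bottom_attractant = attractant("IL-8", "intermediate", 0.4))
  expect_identical(cs$bias_sign, 1)
  expect_identical(cs$dominant, "fMLP")
  # within a class, higher potency wins
  cs2 <- condition_spec("sputum_pair",
                        top_attractant = attractant("control sputum", "intermediate", 0.22),
                        bottom_attractant = attractant("COPD sputum", "intermediate", 0.39))
  expect_identical(cs2$bias_sign, -1)
  # higher fMLP dose strengthens dominance (dose-dependent net bias)
  low <- condition_spec("f10_vs_il8",
                        top_attractant = attractant("fMLP", "terminal", 0.35),
                        bottom_attractant = attractant("IL-8", "intermediate", 0.35))
  high <- condition_spec("f100_vs_il8",
                         top_attractant = attractant("fMLP", "terminal", 0.45),
                         bottom_attractant = attractant("IL-8", "intermediate", 0.35))
  expect_gt(high$effective_kappa, low$effective_kappa)
  # uniform field: no directional cue
  uni <- condition_spec("uniform_il8", uniform = TRUE,
                        top_attractant = attractant("IL-8", "intermediate", 0.35))
  expect_identical(uni$effective_kappa, 0)
})

test_that("cohort generator has the stated ground-truth structure", {
  coh <- generate_cohort(n_copd = 4, n_control = 4, tracks_per_subject = 10,
                         seed = 21)
  s <- coh$subjects
  expect_identical(nrow(s), 8L)
  # COPD sputum more potent on average
  expect_gt(mean(s$kappa[s$group == "COPD"]), mean(s$kappa[s$group == "control"]))
  # potency decreases with FEV1/FVC within COPD
  copd <- s[s$group == "COPD", ]
  expect_lt(cor(copd$fev1_fvc_pct, copd$target_ci), 0)
  # controls have no spirometry, like the measured table
  expect_true(all(is.na(s$fev1_fvc_pct[s$group == "control"])))
  # same seed: identical cohort
  coh2 <- generate_cohort(n_copd = 4, n_control = 4, tracks_per_subject = 10,
                          seed = 21)
  expect_identical(coh, coh2)
  expect_error(generate_cohort(n_copd = 1), "at least 2")
  expect_error(generate_cohort(ci_copd_mean = 1.2), "\\[0, 1\\)")
})

test_that("default cohort separation is detectable by the group t test", {
  # power of the downstream COPD-vs-control t test at the default group
  # means (0.39 vs 0.22): the closed-form oracle for the generator's target
  # C.I. distributions gives ~0.79 at n = 5 + 5, so the pipeline should
  # reject well above the 0.05 baseline. Scaled down (50 replicates, 40-step
  # tracks) to keep the suite fast; track-level noise is minor at 50 tracks
  # per subject.
  cfg_small <- assay_config(n_frames = 41)
  rejects <- vapply(1:50, function(i) {
    coh <- generate_cohort(tracks_per_subject = 50, config = cfg_small,
                           seed = 5000 + i)
    meas <- measure_cohort(coh)
    two_sample_ttest(meas, ci_mean, group)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rejects), 0.6)
})

test_that("noise-free cohort recovers the C.I.-FEV1/FVC line as tracks grow", {
  coh <- generate_cohort(n_copd = 5, n_control = 2, correlation_noise_sd = 0,
                         tracks_per_subject = 300,
                         config = assay_config(
                           geometry = channel_geometry(width = 4000),
                           field_length = 4000),
                         seed = 31)
  meas <- measure_cohort(coh)
  fit <- regress_ci_on_spirometry(meas)
  expect_gt(fit$summary$r_squared, 0.9)
  expect_lt(fit$summary$slope, 0)
})
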