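tb1 <- read_subject_table()

test_that("pooled t test matches closed form and handles degenerate input", {
  df_eq <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  r <- two_sample_ttest(df_eq, v, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # clearly separated groups
  df_sep <- tibble::tibble(v = c(1, 2, 3, 101, 102, 103),
                           g = rep(c("a", "b"), each = 3))
  expect_lt(two_sample_ttest(df_sep, v, g)$p_value, 1e-4)
  # closed form: t = diff / (sp * sqrt(2/n))
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  sp <- sqrt((var(a) * 2 + var(b) * 2) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  r2 <- two_sample_ttest(tibble::tibble(v = c(a, b),
                                        g = rep(c("a", "b"), each = 3)), v, g)
  expect_equal(r2$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r2$df, 4)
  # constant identical groups
  df_const <- tibble::tibble(v = rep(5, 6), g = rep(c("a", "b"), each = 3))
  rc <- two_sample_ttest(df_const, v, g)
  expect_equal(rc$statistic, 0); expect_equal(rc$p_value, 1)
  expect_error(two_sample_ttest(df_eq[1:4, ], v, g), "n >= 2")
  expect_error(two_sample_ttest(tibble::tibble(v = 1:6, g = rep("a", 6)), v, g),
               "2 levels")
})

test_that("measured cohort: COPD C.I. significantly higher than control", {
  r <- two_sample_ttest(tb1, ci_mean, group)
  expect_equal(abs(r$statistic), 3.335, tolerance = 1e-3)
  expect_equal(r$df, 8)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
  # Welch flag changes the df but not the conclusion here
  rw <- two_sample_ttest(tb1, ci_mean, group, welch = TRUE)
  expect_lt(rw$p_value, 0.05)
  expect_false(rw$df == 8)
})

test_that("t test p-values agree with a permutation oracle", {
  a <- tb1$ci_mean[tb1$group == "COPD"]
  b <- tb1$ci_mean[tb1$group == "control"]
  p_perm <- perm_ttest_p(a, b, n_perm = 10000)
  r <- two_sample_ttest(tb1, ci_mean, group)
  # Monte-Carlo error at p ~ 0.01 is ~0.002; allow a generous band
  expect_equal(r$p_value, p_perm, tolerance = 0.01)
})

test_that("one-way ANOVA behaves and reduces to t-squared", {
  withr::with_seed(8, {
    df3 <- tibble::tibble(v = c(rnorm(5), rnorm(5, 3), rnorm(5, 6)),
                          g = rep(c("a", "b", "c"), each = 5))
  })
  r <- one_way_anova(df3, v, g)
  expect_equal(r$df, 2); expect_equal(r$df2, 12)
  expect_lt(r$p_value, 0.05)
  # all-constant groups flagged degenerate
  rconst <- one_way_anova(tibble::tibble(v = rep(1, 9),
                                         g = rep(c("a", "b", "c"), each = 3)), v, g)
  expect_true(is.na(rconst$statistic))
  # < 3 groups: advised to use the t test
  expect_error(one_way_anova(df3[df3$g != "c", ], v, g), "two_sample_ttest")
  # two-group reduction: F = t^2
  df2g <- df3[df3$g != "c", ]
  f2 <- one_way_anova(df2g, v, g, .allow_two = TRUE)
  t2 <- two_sample_ttest(df2g, v, g)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)
})

test_that("ANOVA type-I error is calibrated at alpha = 0.05", {
  withr::with_seed(123, {
    hits <- sum(vapply(1:400, function(i) {
      df <- tibble::tibble(v = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
      one_way_anova(df, v, g)$p_value < 0.05
    }, TRUE))
  })
  expect_lte(abs(hits / 400 - 0.05), 0.025)
})

test_that("spirometry regression reproduces the measured-cohort findings", {
  # collinear points: r^2 = 1
  col <- tibble::tibble(subject_id = letters[1:4], group = "COPD",
                        ci_mean = c(0.5, 0.4, 0.3, 0.2),
                        fev1_fvc_pct = c(40, 50, 60, 70))
  expect_equal(glance(regress_ci_on_spirometry(col))$r_squared, 1)
  # the 4-subject fit excluding the age-57 patient: r^2 >= 0.93, slope < 0
  fit4 <- regress_ci_on_spirometry(tb1, exclude = "COPD3")
  expect_gte(fit4$summary$r_squared, 0.93)
  expect_lt(fit4$summary$slope, 0)
  expect_equal(fit4$summary$r_squared, fit4$summary$pearson_r^2)
  # all 5 patients: weaker than the best 4-subset
  fit5 <- regress_ci_on_spirometry(tb1)
  expect_lt(fit5$summary$r_squared, fit4$summary$r_squared)
  # records without spirometry are excluded with a message
  expect_message(regress_ci_on_spirometry(
    dplyr::mutate(tb1[tb1$group == "COPD", ],
                  fev1_fvc_pct = replace(fev1_fvc_pct, 1, NA))), "Excluding")
  expect_error(regress_ci_on_spirometry(col[1:2, ]), ">= 3")
  # tidy/glance methods
  expect_named(tidy(fit4),
               c("term", "estimate", "std_error", "statistic", "p_value"))
  expect_s3_class(ggplot2::autoplot(fit4), "ggplot")
})

test_that("leave-one-out scan finds the outlying subject", {
  scan <- leave_one_out_scan(tb1)
  expect_identical(nrow(scan), 5L)
  expect_identical(scan$excluded_id[1], "COPD3")  # the age-57 subject
  expect_gte(scan$r_squared[1], 0.93)
  expect_lt(scan$slope[1], 0)
  # sorted by r^2 descending
  expect_true(all(diff(scan$r_squared) <= 0))
  best <- attr(scan, "best_fit")
  expect_identical(sort(best$subset_ids),
                   sort(setdiff(tb1$subject_id[tb1$group == "COPD"], "COPD3")))
  # constructed case: 5 collinear points plus noise on one
  noisy <- tibble::tibble(subject_id = letters[1:5], group = "COPD",
                          fev1_fvc_pct = c(40, 50, 60, 70, 55),
                          ci_mean = c(0.5, 0.4, 0.3, 0.2, 0.9))
  expect_identical(leave_one_out_scan(noisy)$excluded_id[1], "e")
  expect_error(leave_one_out_scan(noisy[1:3, ]), ">= 4")
})

test_that("C.I.-speed correlation is a guarded OLS", {
  # y = x gives r^2 = 1
  df <- tibble::tibble(ci_mean = 1:10 / 10, speed_mean_um_s = 1:10 / 10)
  expect_equal(correlate_ci_speed(df)$r_squared, 1)
  # constant y: r^2 = 0 without error
  dfc <- tibble::tibble(ci_mean = rep(0.3, 5), speed_mean_um_s = 1:5)
  expect_equal(correlate_ci_speed(dfc)$r_squared, 0)
  expect_error(correlate_ci_speed(df[1:2, ]), ">= 3")
  # measured cohort shows no C.I.-speed correlation to speak of
  expect_lt(correlate_ci_speed(tb1)$r_squared, 0.3)
  # independent pairs: r^2 < 0.05 in >= 90% of replicates
  withr::with_seed(77, {
    small <- sum(vapply(1:100, function(i) {
      d <- tibble::tibble(ci_mean = rnorm(200), speed_mean_um_s = rnorm(200))
      correlate_ci_speed(d)$r_squared < 0.05
    }, TRUE))
  })
  expect_gte(small / 100, 0.9)
})

test_that("r^2 is affine invariant and the slope sign flips with x", {
  withr::with_seed(2, {
    d <- tibble::tibble(x = rnorm(20), y = rnorm(20) + 0.5 * x)
  })
  base_fit <- correlate_ci_speed(d, ci = y, speed = x)
  scaled <- correlate_ci_speed(dplyr::mutate(d, x = 3 * x + 7, y = 0.1 * y - 2),
                               ci = y, speed = x)
  expect_equal(scaled$r_squared, base_fit$r_squared, tolerance = 1e-12)
  flipped <- correlate_ci_speed(dplyr::mutate(d, x = -x), ci = y, speed = x)
  expect_equal(flipped$slope, -base_fit$slope, tolerance = 1e-12)
})
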