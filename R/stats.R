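#' Two-sample t test on a tidy table
#'
#' Pooled-variance (Student's) two-sided t test by default, matching the
#' study's stated analysis; Welch's correction is available behind the
#' `welch` flag. Degenerate data (both groups constant) are guarded: equal
#' constants give `statistic = 0, p = 1`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   two-level grouping factor.
#' @param welch Use Welch's unequal-variance t test. Default `FALSE`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `significant` (p < 0.05).
#' @export
#' @examples
#' tb <- read_subject_table()
#' two_sample_ttest(tb, ci_mean, group)
two_sample_ttest <- function(data, value, group, welch = FALSE) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- as.character(g[keep])
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`group` must have exactly 2 levels.")
  a <- v[g == lev[1]]; b <- v[g == lev[2]]
  if (length(a) < 2 || length(b) < 2) abort("Each group needs n >= 2.")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    df <- length(a) + length(b) - 2
    p <- if (is.finite(stat)) 1 else 0
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  tibble(test = if (welch) "welch_t" else "student_t",
         statistic = stat, df = df, p_value = p, significant = p < 0.05)
}

#' One-way ANOVA on a tidy table
#'
#' Classic equal-variance one-way ANOVA for three or more groups. With
#' fewer than 3 groups it errors and advises the t test (use
#' `.allow_two = TRUE` only to verify the F = t² identity). All-constant
#' data are flagged degenerate (`statistic = NA`).
#'
#' @inheritParams two_sample_ttest
#' @param .allow_two Internal; permit exactly 2 groups.
#' @return A one-row tibble: `test`, `statistic` (F), `df`, `df2`,
#'   `p_value`, `significant`.
#' @export
one_way_anova <- function(data, value, group, .allow_two = FALSE) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 3 && !(k == 2 && .allow_two)) {
    abort("one_way_anova() needs >= 3 groups; use two_sample_ttest() for 2.")
  }
  if (any(tapply(v, g, length) < 2)) abort("Each group needs n >= 2.")
  if (stats::sd(v) == 0) {
    return(tibble(test = "anova", statistic = NA_real_, df = k - 1,
                  df2 = length(v) - k, p_value = NA_real_, significant = FALSE))
  }
  fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
  tibble(test = "anova", statistic = unname(fit$statistic),
         df = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
         p_value = fit$p.value, significant = fit$p.value < 0.05)
}

ols_summary <- function(x, y) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(tibble(slope = 0, intercept = mean(y), pearson_r = 0,
                  r_squared = 0, n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  # collinear input triggers lm's "essentially perfect fit" warning; r^2 = 1
  # is exactly the intended answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         pearson_r = sign(unname(coef(fit)[2])) * sqrt(r2),
         r_squared = r2, n = length(x))
}

#' Regress chemotactic index on spirometry
#'
#' Ordinary least squares of per-subject mean C.I. on FEV1/FVC for the COPD
#' subjects, the analysis behind the C.I.–spirometry correlation: a
#' negative slope means stronger chemotaxis with worse airway obstruction.
#' Records without spirometry are excluded (with a message).
#'
#' @param records Subject table with columns `subject_id`, `ci_mean`,
#'   `fev1_fvc_pct` and optionally `group` (non-COPD rows are dropped).
#' @param exclude Optional character vector of `subject_id`s to leave out.
#' @return An object of class `spiro_fit` with `tidy()`, `glance()` and
#'   `autoplot()` methods; `glance()` returns `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `n` and the fitted subject ids.
#' @export
#' @examples
#' tb <- read_subject_table()
#' fit <- regress_ci_on_spirometry(tb)
#' glance(fit)
regress_ci_on_spirometry <- function(records, exclude = NULL) {
  if ("group" %in% names(records)) {
    records <- records[records$group == "COPD", , drop = FALSE]
  }
  if (!is.null(exclude)) {
    records <- records[!records$subject_id %in% exclude, , drop = FALSE]
  }
  miss <- is.na(records$fev1_fvc_pct) | is.na(records$ci_mean)
  if (any(miss)) {
    message(sprintf("Excluding %d record(s) without spirometry: %s",
                    sum(miss), paste(records$subject_id[miss], collapse = ", ")))
    records <- records[!miss, , drop = FALSE]
  }
  if (nrow(records) < 3) abort("Need >= 3 records with spirometry.")
  smry <- ols_summary(records$fev1_fvc_pct, records$ci_mean)
  fit <- stats::lm(ci_mean ~ fev1_fvc_pct, data = records)
  structure(list(fit = fit, data = records, summary = smry,
                 subset_ids = records$subject_id),
            class = "spiro_fit")
}

#' @export
tidy.spiro_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
         statistic = cf[, 3], p_value = cf[, 4])
}

#' @export
glance.spiro_fit <- function(x, ...) {
  out <- x$summary
  out$subset_ids <- paste(x$subset_ids, collapse = ",")
  out
}

#' @export
print.spiro_fit <- function(x, ...) {
  cat("OLS of chemotactic index on FEV1/FVC\n")
  cat(sprintf("  n = %d subjects (%s)\n", x$summary$n,
              paste(x$subset_ids, collapse = ", ")))
  cat(sprintf("  slope = %.5f per %%, r^2 = %.4f\n",
              x$summary$slope, x$summary$r_squared))
  invisible(x)
}

#' @export
autoplot.spiro_fit <- function(object, ...) {
  ggplot(object$data, aes(x = fev1_fvc_pct, y = ci_mean)) +
    geom_point(size = 2.5, colour = "#1b9e77") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "grey40", linewidth = 0.6) +
    labs(x = "FEV1/FVC (×100%)", y = "Chemotactic index",
         title = sprintf("C.I. vs spirometry (r² = %.2f)",
                         object$summary$r_squared)) +
    theme_minimal()
}

#' Leave-one-out regression scan
#'
#' Refits the C.I.–FEV1/FVC regression once per excluded subject and ranks
#' the fits, operationalizing the by-inspection exclusion of an outlying
#' subject as an exhaustive scan: the top row identifies the subject whose
#' removal maximizes r².
#'
#' @inheritParams regress_ci_on_spirometry
#' @return A tibble with one row per excluded subject (`excluded_id`,
#'   `slope`, `intercept`, `pearson_r`, `r_squared`, `n`), sorted by
#'   r² descending then by excluded id. The best fit's `spiro_fit` object
#'   is attached as attribute `"best_fit"`.
#' @export
#' @examples
#' scan <- leave_one_out_scan(read_subject_table())
#' scan$excluded_id[1]
leave_one_out_scan <- function(records) {
  if ("group" %in% names(records)) {
    records <- records[records$group == "COPD", , drop = FALSE]
  }
  records <- records[!is.na(records$fev1_fvc_pct) & !is.na(records$ci_mean), ,
                     drop = FALSE]
  if (nrow(records) < 4) abort("Need >= 4 records for a leave-one-out scan.")
  out <- map_dfr(records$subject_id, function(id) {
    keep <- records[records$subject_id != id, , drop = FALSE]
    tibble(excluded_id = id, ols_summary(keep$fev1_fvc_pct, keep$ci_mean))
  })
  out <- out |> arrange(desc(r_squared), excluded_id)
  attr(out, "best_fit") <-
    regress_ci_on_spirometry(records, exclude = out$excluded_id[1])
  out
}

#' Correlation between chemotactic index and migration speed
#'
#' OLS of C.I. on speed — used to verify that directionality and motility
#' are independent read-outs (near-zero r² on cohorts generated with
#' independent C.I. and speed).
#'
#' @param data A data frame of per-subject or per-track pairs.
#' @param ci,speed Columns (tidy-eval). Defaults `ci_mean`,
#'   `speed_mean_um_s`.
#' @return A one-row tibble: `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `n`.
#' @export
correlate_ci_speed <- function(data, ci = ci_mean, speed = speed_mean_um_s) {
  y <- dplyr::pull(data, {{ ci }})
  x <- dplyr::pull(data, {{ speed }})
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) abort("Need >= 3 complete pairs.")
  ols_summary(x[keep], y[keep])
}
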