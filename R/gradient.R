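#' Steady cross-channel gradient profile from co-flow mixing
#'
#' Two streams of equal flow — one carrying chemoattractant at concentration
#' c0, one plain medium — enter the migration channel side by side. At a
#' point a distance `downstream_distance` from the junction, the fluid has
#' been mixing by cross-channel diffusion for an effective time
#' `tau = downstream_distance / mean_flow_speed`, so the profile across the
#' width is the 1-D diffusion of an initial step (c = c0 for `y < width/2`,
#' 0 otherwise) with no-flux walls. The no-flux boundaries are imposed by an
#' image-source series, truncated when terms fall below 1e-12.
#'
#' @param geometry A [channel_geometry()].
#' @param diffusivity Diffusivity in µm²/s. Default 100 (1e-10 m²/s, the
#'   scale of a 10 kDa dextran used for calibration).
#' @param mean_flow_speed Mean downstream flow speed in µm/s.
#' @param downstream_distance Distance from the junction in µm.
#' @param n_points Number of equally spaced sample positions across the width.
#'
#' @return A tibble of class `gradient_profile` with columns `y_um` and
#'   `c_over_c0`, and attributes `width` and `effective_time` (s).
#' @export
#' @examples
#' geom <- channel_geometry()
#' prof <- steady_profile(geom, diffusivity = 100, mean_flow_speed = 500,
#'                        downstream_distance = 5000)
#' mean(prof$c_over_c0)  # mass conservation: 0.5
steady_profile <- function(geometry, diffusivity = 100, mean_flow_speed = 500,
                           downstream_distance = 5000, n_points = 101) {
  stopifnot(inherits(geometry, "channel_geometry"))
  check_number(diffusivity, "diffusivity", positive = TRUE)
  check_number(mean_flow_speed, "mean_flow_speed", positive = TRUE)
  check_number(downstream_distance, "downstream_distance", positive = TRUE)
  if (n_points < 2) abort("`n_points` must be >= 2.")
  tau <- downstream_distance / mean_flow_speed
  w <- geometry$width
  y <- seq(0, w, length.out = n_points)
  c_rel <- profile_at_tau(y, w, diffusivity, tau)
  structure(
    tibble(y_um = y, c_over_c0 = c_rel),
    class = c("gradient_profile", class(tibble())),
    width = w, effective_time = tau
  )
}

# diffusion of the half-width step with no-flux walls at 0 and w. Short
# mixing times use the image-source (erf) series over the even-periodic
# extension ("source" intervals [2kw - w/2, 2kw + w/2]); long mixing times
# switch to the Fourier cosine eigenfunction series, which then converges
# in a handful of terms. Both truncate terms below 1e-12.
profile_at_tau <- function(y, w, D, tau) {
  if (!is.finite(tau)) return(rep(0.5, length(y)))
  s <- sqrt(D * tau)
  if (s == 0) {
    c_rel <- as.numeric(y < w / 2)
    c_rel[y == w / 2] <- 0.5
    return(c_rel)
  }
  if (s >= w / 4) {
    # cosine series: c = 1/2 + sum over odd n of
    # (2/(n pi)) (-1)^((n-1)/2) cos(n pi y / w) exp(-D (n pi / w)^2 tau)
    c_rel <- rep(0.5, length(y))
    n <- 1L
    repeat {
      decay <- exp(-D * (n * pi / w)^2 * tau)
      amp <- 2 / (n * pi) * (-1)^((n - 1) / 2)
      if (abs(amp) * decay < 1e-12) break
      c_rel <- c_rel + amp * decay * cos(n * pi * y / w)
      n <- n + 2L
    }
  } else {
    # images further than ~6 diffusion lengths contribute < 1e-12
    K <- ceiling((6 * s + w) / (2 * w)) + 1L
    c_rel <- rep(0, length(y))
    for (k in -K:K) {
      l <- 2 * k * w - w / 2
      r <- 2 * k * w + w / 2
      c_rel <- c_rel + 0.5 * (erf((y - l) / (2 * s)) - erf((y - r) / (2 * s)))
    }
  }
  pmin(pmax(c_rel, 0), 1)
}

#' Time for the gradient to be established at a downstream station
#'
#' Before the co-flow front has been advected to the observation point there
#' is no chemoattractant there at all; the front spreads axially by diffusion
#' as it travels. The transient profile at wall time `T` is modeled as the
#' steady profile scaled by the front passage factor
#' `F(T) = 0.5 * erfc((L - v T) / (2 sqrt(D T)))`, and the establishment time
#' is the smallest `T >= L / v` at which the maximum pointwise deviation from
#' the steady profile, `(1 - F(T)) * max(c/c0)`, drops below `tolerance`.
#'
#' @inheritParams steady_profile
#' @param tolerance Maximum allowed pointwise deviation from the steady
#'   profile, as a fraction of c0; in `(0, 1]`.
#' @return Establishment time in seconds (always >= the advection time
#'   `downstream_distance / mean_flow_speed`).
#' @export
establishment_time <- function(geometry, diffusivity = 100, mean_flow_speed = 500,
                               downstream_distance = 5000, tolerance = 0.05) {
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      tolerance <= 0 || tolerance > 1) {
    abort("`tolerance` must be in (0, 1].")
  }
  prof <- steady_profile(geometry, diffusivity, mean_flow_speed,
                         downstream_distance, n_points = 201)
  cmax <- max(prof$c_over_c0)
  t_adv <- downstream_distance / mean_flow_speed
  dev <- function(t) {
    front <- 0.5 * (1 + erf((mean_flow_speed * t - downstream_distance) /
                              (2 * sqrt(diffusivity * t))))
    (1 - front) * cmax
  }
  if (dev(t_adv) <= tolerance) return(t_adv)
  hi <- t_adv * 2
  while (dev(hi) > tolerance) hi <- hi * 2
  stats::uniroot(function(t) dev(t) - tolerance, c(t_adv, hi), tol = 1e-9)$root
}

#' Export a gradient profile as two-column delimited text
#'
#' Writes columns `y_um` and `c_over_c0` (tab separated). With
#' `noise_sd > 0`, Gaussian read noise is added to emulate a fluorescence
#' calibration readout.
#'
#' @param profile A `gradient_profile`.
#' @param path Output path.
#' @param noise_sd Read-noise standard deviation (fraction of c0). Default 0.
#' @param seed Optional RNG seed for the noise.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, noise_sd = 0, seed = NULL) {
  out <- tibble(y_um = profile$y_um, c_over_c0 = profile$c_over_c0)
  if (noise_sd > 0) {
    out$c_over_c0 <- with_seed_if(seed,
      out$c_over_c0 + stats::rnorm(nrow(out), 0, noise_sd))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot a gradient profile
#'
#' @param object A `gradient_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gradient_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$y_um, y = .data$c_over_c0)) +
    geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    labs(
      x = "cross-channel position y (µm)",
      y = "c / c0",
      title = sprintf("Gradient profile (effective mixing time %.1f s)",
                      attr(object, "effective_time"))
    ) +
    ylim(0, 1) +
    theme_minimal()
}
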