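# fold a coordinate into [0, w] -- exact specular reflection of the
# straight-line path at the channel walls
fold_reflect <- function(z, w) {
  r <- z %% (2 * w)
  ifelse(r > w, 2 * w - r, r)
}

draw_speeds <- function(n, motility) {
  if (is.infinite(motility$speed_shape)) {
    rep(motility$mean_step_speed, n)
  } else {
    stats::rgamma(n, shape = motility$speed_shape,
                  rate = motility$speed_shape / motility$mean_step_speed)
  }
}

#' Simulate one gradient-biased cell track
#'
#' A biased persistent random walk: per step the direction is von Mises
#' about the bias direction (blended with the previous step's direction when
#' `persistence > 0`), the step length is `speed * frame_interval` with speed
#' drawn from a Gamma law, and positions are specularly reflected at the
#' channel walls (`y` in `[0, width]`, `x` in `[0, field_length]`).
#'
#' @param motility A [motility_params()].
#' @param config An [assay_config()].
#' @param start Length-2 start position `c(x, y)` in µm; must lie inside the
#'   field. Default: field centre.
#' @param bias_direction Unit vector of the bias; defaults to the config's
#'   gradient axis.
#' @param seed Optional RNG seed; the track is fully reproducible from it.
#' @param track_id,condition Identifiers carried into the output.
#' @return A tibble with columns `track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `condition` (`config$n_frames` rows).
#' @export
#' @examples
#' trk <- simulate_track(motility_params(kappa = 2), assay_config(), seed = 1)
#' chemotactic_index(trk, c(0, -1))
simulate_track <- function(motility, config, start = NULL,
                           bias_direction = NULL, seed = NULL,
                           track_id = 1L, condition = "condition") {
  tr <- simulate_tracks(1L, motility, config,
                        bias_direction = bias_direction,
                        start = if (is.null(start)) NULL else matrix(start, nrow = 1),
                        condition = condition, seed = seed)
  tr$track_id <- as.integer(track_id)
  tr
}

#' Simulate a population of gradient-biased tracks
#'
#' Vectorized version of [simulate_track()]; all tracks share the motility
#' parameters and bias direction.
#'
#' @inheritParams simulate_track
#' @param n_tracks Number of tracks.
#' @param start Either `NULL` (random uniform starts inside the field) or an
#'   `n_tracks` x 2 matrix of `c(x, y)` starts in µm.
#' @return A tibble in the track-table dialect: `track_id`, `frame`,
#'   `time_s`, `x_um`, `y_um`, `condition`.
#' @export
simulate_tracks <- function(n_tracks, motility, config, bias_direction = NULL,
                            start = NULL, condition = "condition", seed = NULL) {
  stopifnot(inherits(motility, "motility_params"), inherits(config, "assay_config"))
  n_tracks <- as.integer(n_tracks)
  if (n_tracks < 1L) abort("`n_tracks` must be >= 1.")
  bias <- unit_vector(bias_direction %||% config$gradient_axis, "bias_direction")
  w <- config$geometry$width
  fl <- config$field_length
  m <- config$n_frames - 1L  # steps
  dt <- config$frame_interval

  with_seed_if(seed, {
    if (is.null(start)) {
      start <- cbind(stats::runif(n_tracks, 0, fl), stats::runif(n_tracks, 0, w))
    } else {
      start <- matrix(start, ncol = 2)
      if (nrow(start) != n_tracks) abort("`start` must have one row per track.")
      if (any(start[, 1] < 0 | start[, 1] > fl | start[, 2] < 0 | start[, 2] > w)) {
        abort("`start` positions must lie inside the channel field.")
      }
    }
    mu <- atan2(bias[2], bias[1])
    speeds <- matrix(draw_speeds(n_tracks * m, motility), nrow = m)
    if (motility$persistence == 0) {
      ang <- matrix(rvonmises(n_tracks * m, mu, motility$kappa), nrow = m)
    } else {
      # sequential: mean direction blends bias with previous direction
      p <- motility$persistence
      ang <- matrix(0, nrow = m, ncol = n_tracks)
      prev <- matrix(rep(bias, each = n_tracks), ncol = 2)
      for (i in seq_len(m)) {
        blend <- cbind((1 - p) * bias[1] + p * prev[, 1],
                       (1 - p) * bias[2] + p * prev[, 2])
        mu_i <- atan2(blend[, 2], blend[, 1])
        dev <- rvonmises(n_tracks, 0, motility$kappa)
        ang[i, ] <- mu_i + dev
        prev <- cbind(cos(ang[i, ]), sin(ang[i, ]))
      }
    }
    dx <- speeds * dt * cos(ang)
    dy <- speeds * dt * sin(ang)
    x <- rbind(start[, 1], sweep(apply(dx, 2, cumsum), 2, start[, 1], `+`))
    y <- rbind(start[, 2], sweep(apply(dy, 2, cumsum), 2, start[, 2], `+`))
    if (m == 1L) {  # apply() drops dims
      x <- rbind(start[, 1], start[, 1] + dx[1, ])
      y <- rbind(start[, 2], start[, 2] + dy[1, ])
    }
    x <- fold_reflect(x, fl)
    y <- fold_reflect(y, w)
    tibble(
      track_id = rep(seq_len(n_tracks), each = m + 1L),
      frame = rep(seq_len(m + 1L), times = n_tracks),
      time_s = rep((0:m) * dt, times = n_tracks),
      x_um = as.vector(x),
      y_um = as.vector(y),
      condition = condition
    )
  })
}

#' Plot tracks as a spider (origin-translated) plot
#'
#' Each track is translated so it starts at the origin; the gradient axis is
#' drawn as an arrow.
#'
#' @param tracks A track tibble.
#' @param gradient_axis Optional unit vector to annotate.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, gradient_axis = NULL) {
  cent <- tracks |>
    group_by(track_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(x0 = .data$x_um - first(.data$x_um),
           y0 = .data$y_um - first(.data$y_um)) |>
    ungroup()
  p <- ggplot(cent, aes(x = x0, y = y0, group = track_id)) +
    geom_path(alpha = 0.4, colour = "grey30") +
    coord_equal() +
    labs(x = "Δx (µm)", y = "Δy (µm)", title = "Origin-translated tracks") +
    theme_minimal()
  if (!is.null(gradient_axis)) {
    g <- unit_vector(gradient_axis)
    r <- max(abs(c(cent$x0, cent$y0)))
    p <- p + annotate("segment", x = 0, y = 0, xend = g[1] * r * 0.5,
                      yend = g[2] * r * 0.5, colour = "#d95f02",
                      arrow = grid::arrow(length = grid::unit(3, "mm")))
  }
  p
}
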