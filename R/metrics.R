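#' Chemotactic index of a single track
#'
#' The chemotactic index (C.I.) is the signed ratio of a track's net
#' displacement along the gradient axis to its total path length: 1 for a
#' straight run up-gradient, 0 for undirected motion, negative for net
#' movement down-gradient. A stationary track (zero path length) has an
#' undefined C.I. and returns `NA`.
#'
#' @param track A data frame with columns `x_um`, `y_um` (and optionally
#'   `frame`/`time_s` used to order the samples); at least 2 rows.
#' @param gradient_axis Length-2 unit vector pointing up-gradient.
#' @return A number in `[-1, 1]`, or `NA` for a stationary track.
#' @export
#' @examples
#' trk <- tibble::tibble(x_um = c(0, 3, 3), y_um = c(0, 4, 10))
#' chemotactic_index(trk, c(0, 1))  # 10/11
chemotactic_index <- function(track, gradient_axis) {
  g <- unit_vector(gradient_axis)
  track <- order_track(track)
  if (nrow(track) < 2) abort("A track needs at least 2 samples.")
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  path <- sum(sqrt(dx^2 + dy^2))
  if (path == 0) return(NA_real_)
  net <- c(sum(dx), sum(dy))
  sum(net * g) / path
}

#' Migration speed of a single track
#'
#' Total path length divided by the track's own duration
#' (`t_last - t_first`); pauses count toward the denominator.
#'
#' @param track A data frame with columns `time_s`, `x_um`, `y_um`;
#'   at least 2 rows.
#' @return Speed in µm/s.
#' @export
#' @examples
#' trk <- tibble::tibble(time_s = c(0, 10, 110), x_um = c(0, 3, 3),
#'                       y_um = c(0, 4, 10))
#' migration_speed(trk)  # 11/110
migration_speed <- function(track) {
  track <- order_track(track)
  if (nrow(track) < 2) abort("A track needs at least 2 samples.")
  dur <- track$time_s[nrow(track)] - track$time_s[1]
  if (!is.finite(dur) || dur <= 0) abort("Track duration must be > 0.")
  path <- sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
  path / dur
}

order_track <- function(track) {
  if ("time_s" %in% names(track)) {
    track[order(track$time_s), , drop = FALSE]
  } else if ("frame" %in% names(track)) {
    track[order(track$frame), , drop = FALSE]
  } else {
    track
  }
}

#' Per-track chemotactic index and speed
#'
#' Computes the two migration statistics for every track in a track table.
#' Uses a vectorized fast path (no per-track loop), so it scales to large
#' simulated populations.
#'
#' @param tracks A track tibble with columns `track_id`, `time_s`, `x_um`,
#'   `y_um` and optionally `condition`.
#' @param gradient_axis Length-2 unit vector pointing up-gradient.
#' @return A tibble with one row per track: `track_id`, `condition` (if
#'   present), `n_frames`, `ci`, `speed_um_s`. Stationary tracks have
#'   `ci = NA`.
#' @export
track_metrics <- function(tracks, gradient_axis) {
  g <- unit_vector(gradient_axis)
  need <- c("track_id", "time_s", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    abort(sprintf("`tracks` must have columns %s.", paste(need, collapse = ", ")))
  }
  keys <- if ("subject_id" %in% names(tracks)) {
    paste(tracks$subject_id, tracks$track_id, sep = "\r")
  } else {
    as.character(tracks$track_id)
  }
  ord <- order(keys, tracks$time_s)
  id <- keys[ord]
  x <- tracks$x_um[ord]; y <- tracks$y_um[ord]; t <- tracks$time_s[ord]
  n <- length(id)
  same <- id[-1] == id[-n]
  dx <- diff(x)[same]; dy <- diff(y)[same]
  seg <- sqrt(dx^2 + dy^2)
  ids_u <- unique(id)
  path <- stats::setNames(rep(0, length(ids_u)), ids_u)
  if (length(seg)) {
    pb <- rowsum(seg, id[-1][same])
    path[rownames(pb)] <- pb[, 1]
  }
  firsts <- !duplicated(id)
  lasts <- !duplicated(id, fromLast = TRUE)
  net_g <- (x[lasts] - x[firsts]) * g[1] + (y[lasts] - y[firsts]) * g[2]
  dur <- t[lasts] - t[firsts]
  nf <- tabulate(match(id, ids_u))
  out <- tibble(
    track_id = tracks$track_id[ord][firsts],
    n_frames = nf,
    ci = unname(ifelse(path > 0, net_g / path, NA_real_)),
    speed_um_s = unname(ifelse(dur > 0, path / dur, NA_real_))
  )
  if ("subject_id" %in% names(tracks)) {
    out <- tibble(subject_id = tracks$subject_id[ord][firsts], out)
  }
  if ("condition" %in% names(tracks)) {
    out$condition <- tracks$condition[ord][firsts]
  }
  out
}

#' Per-condition summary of migration statistics
#'
#' Pools all tracks of each condition and reports mean ± SEM (over tracks)
#' of the chemotactic index and speed. Tracks with an undefined C.I.
#' (stationary cells) are excluded from the C.I. aggregate and counted in
#' `n_excluded`.
#'
#' @inheritParams track_metrics
#' @return A tibble with one row per condition: `condition`, `n_tracks`,
#'   `n_excluded`, `mean_ci`, `sem_ci`, `mean_speed_um_s`, `sem_speed_um_s`.
#' @export
summarize_conditions <- function(tracks, gradient_axis) {
  metrics <- track_metrics(tracks, gradient_axis)
  if (!"condition" %in% names(metrics)) metrics$condition <- "condition"
  if (all(is.na(metrics$ci))) abort("No track has a defined chemotactic index.")
  metrics |>
    group_by(condition) |>
    summarise(
      n_tracks = sum(!is.na(.data$ci)),
      n_excluded = sum(is.na(.data$ci)),
      mean_ci = mean(.data$ci, na.rm = TRUE),
      sem_ci = stats::sd(.data$ci[!is.na(.data$ci)]) / sqrt(sum(!is.na(.data$ci))),
      mean_speed_um_s = mean(.data$speed_um_s, na.rm = TRUE),
      sem_speed_um_s = stats::sd(.data$speed_um_s, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$speed_um_s))),
      .groups = "drop"
    )
}
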