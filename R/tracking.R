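#' Otsu threshold of an image
#'
#' Global threshold maximizing the between-class variance of the gray-level
#' histogram (256 bins over the observed range).
#'
#' @param x Numeric matrix or vector of gray levels.
#' @param n_bins Number of histogram bins. Default 256.
#' @return The threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill with batched (vectorized) frontiers; labels are
#' assigned in raster-scan order of each component's first pixel, so the
#' result is deterministic.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  lab <- integer(nr * nc)
  if (length(fg) == 0) return(matrix(lab, nr, nc))
  in_fg <- logical(nr * nc); in_fg[fg] <- TRUE
  cur <- 0L
  for (seed_px in fg) {
    if (lab[seed_px] != 0L) next
    cur <- cur + 1L
    frontier <- seed_px
    lab[seed_px] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      up <- frontier[r > 1L] - 1L
      dn <- frontier[r < nr] + 1L
      lf <- frontier - nr
      rt <- frontier + nr
      nbr <- c(up, dn, lf[lf >= 1L], rt[rt <= nr * nc])
      if (connectivity == 8) {
        ul <- (frontier[r > 1L] - 1L) - nr
        ur <- (frontier[r > 1L] - 1L) + nr
        dl <- (frontier[r < nr] + 1L) - nr
        dr <- (frontier[r < nr] + 1L) + nr
        diag <- c(ul, ur, dl, dr)
        nbr <- c(nbr, diag[diag >= 1L & diag <= nr * nc])
      }
      nbr <- unique(nbr)
      nbr <- nbr[in_fg[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  matrix(lab, nr, nc)
}

# fill holes: background components not touching the image border become
# foreground (4-connectivity for the background)
fill_holes <- function(mask) {
  bg_lab <- label_components(!mask, connectivity = 4)
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                     bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border <- border[border != 0]
  mask | (bg_lab != 0 & !(bg_lab %in% border))
}

segment_frame <- function(frame, min_area, pixel_size) {
  th <- otsu_threshold(frame)
  mask <- frame > th
  mask <- fill_holes(mask)
  lab <- label_components(mask, connectivity = 8)
  if (min_area > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes * pixel_size^2 < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab
}

#' Detect cell positions in a single frame
#'
#' In `"label"` mode, returns the exact centroid of every labelled region.
#' In `"threshold"` mode, segments the grayscale frame with an Otsu
#' threshold, fills holes, removes components smaller than `min_area`, and
#' returns the component centroids. Positions are in µm with 0-based pixel
#' centres (`x = (col - 1) * pixel_size`).
#'
#' @param frame Numeric matrix (gray) or integer matrix (labels).
#' @param mode `"label"` or `"threshold"`.
#' @param min_area Minimum region area in µm². Default 20.
#' @param pixel_size Pixel size in µm. Default 1.
#' @return A tibble with columns `x_um`, `y_um`, `area_um2`, `label`
#'   (possibly 0 rows for an empty frame).
#' @export
detect_cells <- function(frame, mode = c("label", "threshold"),
                         min_area = 20, pixel_size = 1) {
  mode <- match.arg(mode)
  labels <- if (mode == "label") frame else segment_frame(frame, min_area, pixel_size)
  idx <- which(labels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), label = integer(0)))
  }
  lab <- labels[idx]
  xs <- tapply((idx[, 2] - 1) * pixel_size, lab, mean)
  ys <- tapply((idx[, 1] - 1) * pixel_size, lab, mean)
  ns <- tapply(rep(1, length(lab)), lab, sum)
  out <- tibble(
    x_um = as.numeric(xs), y_um = as.numeric(ys),
    area_um2 = as.numeric(ns) * pixel_size^2,
    label = as.integer(names(xs))
  )
  out <- out[out$area_um2 >= if (mode == "label") 0 else min_area, , drop = FALSE]
  out[order(out$label), , drop = FALSE]
}

#' Detect cells in every frame of a stack
#'
#' @param stack A list of matrices, one per frame.
#' @inheritParams detect_cells
#' @return A tibble with a `frame` column prepended to the [detect_cells()]
#'   columns.
#' @export
detect_stack <- function(stack, mode = c("label", "threshold"),
                         min_area = 20, pixel_size = 1) {
  mode <- match.arg(mode)
  map_dfr(seq_along(stack), function(f) {
    d <- detect_cells(stack[[f]], mode = mode, min_area = min_area,
                      pixel_size = pixel_size)
    if (nrow(d)) tibble(frame = f, d) else tibble()
  })
}

#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-pair assignment between consecutive frames:
#' candidate pairs are sorted by distance (ties broken by detection then
#' track centroid, lexicographically), pairs farther than
#' `max_displacement` are never linked, unassigned detections start new
#' tracks, and tracks unmatched for more than `max_gap` frames are closed.
#' The result is deterministic and invariant to the order of detections
#' within a frame.
#'
#' @param detections A tibble with columns `frame`, `x_um`, `y_um`
#'   ([detect_stack()] output).
#' @param max_displacement Maximum per-transition displacement in µm.
#' @param max_gap Frames a track may go undetected before it is closed.
#'   Default 0.
#' @param min_length Minimum track length in frames; shorter tracks are
#'   discarded. Default 10.
#' @param frame_interval If given, a `time_s = (frame - 1) * frame_interval`
#'   column is added.
#' @return A track tibble: `track_id`, `frame`, (`time_s`,) `x_um`, `y_um`.
#' @export
link_tracks <- function(detections, max_displacement, max_gap = 0,
                        min_length = 10, frame_interval = NULL) {
  check_number(max_displacement, "max_displacement", positive = TRUE)
  if (nrow(detections) == 0) {
    return(tibble(track_id = integer(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0)))
  }
  det <- detections[order(detections$frame, detections$x_um, detections$y_um), ]
  frames <- sort(unique(det$frame))
  # active track state
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0); tr_last <- integer(0)
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(cur)
    cand <- which(tr_last >= f - 1L - max_gap & tr_last < f)
    assign_det <- rep(NA_integer_, nd)
    if (length(cand) && nd) {
      dmat <- outer(cur$x_um, tr_x[cand], `-`)^2 + outer(cur$y_um, tr_y[cand], `-`)^2
      ok <- which(dmat <= max_displacement^2, arr.ind = TRUE)
      if (nrow(ok)) {
        o <- ok[order(dmat[ok], cur$x_um[ok[, 1]], cur$y_um[ok[, 1]],
                      tr_x[cand][ok[, 2]], tr_y[cand][ok[, 2]]), , drop = FALSE]
        used_d <- logical(nd); used_t <- logical(length(cand))
        for (r in seq_len(nrow(o))) {
          di <- o[r, 1]; ti <- o[r, 2]
          if (!used_d[di] && !used_t[ti]) {
            used_d[di] <- TRUE; used_t[ti] <- TRUE
            assign_det[di] <- cand[ti]
          }
        }
      }
    }
    ids <- integer(nd)
    for (j in seq_len(nd)) {
      if (is.na(assign_det[j])) {
        tr_id <- c(tr_id, next_id); tr_x <- c(tr_x, 0); tr_y <- c(tr_y, 0)
        tr_last <- c(tr_last, 0L)
        assign_det[j] <- length(tr_id)
        ids[j] <- next_id
        next_id <- next_id + 1L
      } else {
        ids[j] <- tr_id[assign_det[j]]
      }
      tr_x[assign_det[j]] <- cur$x_um[j]
      tr_y[assign_det[j]] <- cur$y_um[j]
      tr_last[assign_det[j]] <- f
    }
    if (nd) rows[[fi]] <- tibble(track_id = ids, frame = f,
                                 x_um = cur$x_um, y_um = cur$y_um)
  }
  out <- bind_rows(rows)
  keep <- out |> count(track_id) |> filter(n >= min_length) |> pull(track_id)
  out <- out[out$track_id %in% keep, , drop = FALSE]
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  if (!is.null(frame_interval)) out$time_s <- (out$frame - 1) * frame_interval
  out
}
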