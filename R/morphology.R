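# second-order central moments of a pixel region (0-based pixel centres)
region_shape <- function(rows, cols, pixel_size) {
  n <- length(rows)
  cx <- mean(cols - 1); cy <- mean(rows - 1)
  dx <- (cols - 1) - cx; dy <- (rows - 1) - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  degenerate <- n < 5 || l2 <= 1e-12
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  tibble(
    area_um2 = n * pixel_size^2,
    x_um = cx * pixel_size,
    y_um = cy * pixel_size,
    major_um = 4 * sqrt(pmax(l1, 0)) * pixel_size,
    minor_um = 4 * sqrt(pmax(l2, 0)) * pixel_size,
    orientation = theta,
    aspect_ratio = if (degenerate) NA_real_ else sqrt(l1 / l2),
    degenerate = degenerate
  )
}

#' Fit the moment-equivalent ellipse to a binary region
#'
#' Computes the second-order central moments of the filled region and
#' reports the ellipse with the same moments (the same convention Fiji's
#' "fit ellipse" uses): full axes `4 * sqrt(lambda)` for the two eigenvalues
#' of the moment matrix, aspect ratio `sqrt(lambda1 / lambda2)`, and
#' orientation from the principal eigenvector (in `(-pi/2, pi/2]`, measured
#' in the x-y plane). One-dimensional (degenerate) regions are flagged and
#' get an undefined aspect ratio.
#'
#' @param mask A logical (or 0/1) matrix; rows index y, columns x.
#' @param pixel_size Pixel size in µm. Default 1.
#' @return A one-row tibble: `area_um2`, `x_um`, `y_um`, `major_um`,
#'   `minor_um`, `orientation`, `aspect_ratio`, `degenerate`.
#' @export
#' @examples
#' disk <- outer(-20:20, -20:20, function(i, j) i^2 + j^2 <= 15^2)
#' fit_ellipse(disk)$aspect_ratio  # ~1
fit_ellipse <- function(mask, pixel_size = 1) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 5) abort("Region must have at least 5 pixels.")
  region_shape(idx[, 1], idx[, 2], pixel_size)
}

#' Measure every labelled region in a label image
#'
#' @param labels Integer matrix; 0 = background, each positive integer one
#'   region.
#' @param pixel_size Pixel size in µm.
#' @param min_area Minimum region area in µm²; smaller regions are dropped.
#' @return A tibble with one row per region (`label` plus the
#'   [fit_ellipse()] columns). Regions with fewer than 5 pixels or
#'   degenerate geometry keep `aspect_ratio = NA` and `degenerate = TRUE`.
#' @export
measure_labels <- function(labels, pixel_size = 1, min_area = 0) {
  idx <- which(labels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(tibble())
  lab <- labels[idx]
  split_rows <- split(seq_len(nrow(idx)), lab)
  out <- map_dfr(names(split_rows), function(l) {
    rc <- idx[split_rows[[l]], , drop = FALSE]
    if (nrow(rc) < 5) {
      return(tibble(label = as.integer(l), area_um2 = nrow(rc) * pixel_size^2,
                    x_um = mean(rc[, 2] - 1) * pixel_size,
                    y_um = mean(rc[, 1] - 1) * pixel_size,
                    major_um = NA_real_, minor_um = NA_real_,
                    orientation = NA_real_, aspect_ratio = NA_real_,
                    degenerate = TRUE))
    }
    tibble(label = as.integer(l), region_shape(rc[, 1], rc[, 2], pixel_size))
  })
  out[out$area_um2 >= min_area, , drop = FALSE]
}

#' Per-condition aspect-ratio summary from an image stack
#'
#' Segments the chosen frame (or measures its label image directly) and
#' reports the mean ± SEM aspect ratio across cells — the morphometric
#' read-out used to distinguish polarized, elongated cells from round
#' unpolarized ones. The default frame is the last of the sequence, i.e.
#' the end of the migration experiment.
#'
#' @param stack A list of matrices (one per frame), or a single matrix.
#' @param pixel_size Pixel size in µm.
#' @param frame Frame to measure: `"last"` (default) or an integer index.
#' @param mode `"label"` if the stack holds label images, `"threshold"` to
#'   segment grayscale frames (Otsu + hole filling, see [detect_cells()]).
#' @param min_area Minimum region area in µm². Default 20.
#' @return A one-row tibble: `n_cells`, `n_degenerate`, `mean_aspect_ratio`,
#'   `sem_aspect_ratio`. The per-cell table is attached as attribute
#'   `"cells"`.
#' @export
measure_condition <- function(stack, pixel_size = 1, frame = "last",
                              mode = c("label", "threshold"), min_area = 20) {
  mode <- match.arg(mode)
  if (is.matrix(stack)) stack <- list(stack)
  fi <- if (identical(frame, "last")) length(stack) else as.integer(frame)
  img <- stack[[fi]]
  labels <- if (mode == "label") img else segment_frame(img, min_area, pixel_size)
  cells <- measure_labels(labels, pixel_size, min_area = min_area)
  valid <- cells[!is.na(cells$aspect_ratio), , drop = FALSE]
  if (nrow(valid) == 0) abort("No valid (non-degenerate) regions to measure.")
  out <- tibble(
    n_cells = nrow(valid),
    n_degenerate = sum(is.na(cells$aspect_ratio)),
    mean_aspect_ratio = mean(valid$aspect_ratio),
    sem_aspect_ratio = stats::sd(valid$aspect_ratio) / sqrt(nrow(valid))
  )
  attr(out, "cells") <- cells
  out
}
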