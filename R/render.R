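# rasterize one filled (optionally ragged) rotated ellipse into label and
# gray matrices; pixel centres are at 0-based integer coordinates * pixel_size
draw_ellipse <- function(labels, gray, cx, cy, a, b, angle, id, ps,
                         fg, boundary_noise = 0) {
  nr <- nrow(labels); nc <- ncol(labels)
  rmax <- max(a, b)
  r0 <- max(1L, floor((cy - rmax) / ps) + 1L)
  r1 <- min(nr, ceiling((cy + rmax) / ps) + 1L)
  c0 <- max(1L, floor((cx - rmax) / ps) + 1L)
  c1 <- min(nc, ceiling((cx + rmax) / ps) + 1L)
  if (r0 > r1 || c0 > c1) return(list(labels = labels, gray = gray))
  ys <- (r0:r1 - 1) * ps - cy
  xs <- (c0:c1 - 1) * ps - cx
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  q <- (u / a)^2 + (v / b)^2
  thr <- 1
  if (boundary_noise > 0) {
    thr <- (1 + stats::rnorm(length(q), 0, boundary_noise))^2
  }
  inside <- q <= thr
  sub_l <- labels[r0:r1, c0:c1, drop = FALSE]
  sub_g <- gray[r0:r1, c0:c1, drop = FALSE]
  sub_l[inside] <- id
  sub_g[inside] <- fg
  labels[r0:r1, c0:c1] <- sub_l
  gray[r0:r1, c0:c1] <- sub_g
  list(labels = labels, gray = gray)
}

ellipse_axes <- function(shape) {
  a <- sqrt(shape$area * shape$aspect_ratio / pi)  # semi-major, µm
  b <- sqrt(shape$area / (pi * shape$aspect_ratio))
  c(a = a, b = b)
}

finish_gray <- function(gray, noise_sd) {
  if (noise_sd > 0) gray <- gray + stats::rnorm(length(gray), 0, noise_sd)
  matrix(as.integer(pmin(pmax(round(gray), 0), 65535)),
         nrow = nrow(gray), ncol = ncol(gray))
}

#' Render a static field of synthetic cells
#'
#' Draws `n_cells` filled rotated ellipses with the given ground-truth shape
#' on a jittered grid whose spacing guarantees centres at least two major
#' axes apart (so cells never touch), then adds Gaussian read noise. This is
#' the fixture generator for the morphology stage: the returned label image
#' and ground-truth table make the measurement loop closable.
#'
#' @param n_cells Number of cells.
#' @param shape A [shape_params()]; `orientation_mode = "gradient_aligned"`
#'   is treated as `"random"` for a static field.
#' @param pixel_size Pixel size in µm. Default 0.5.
#' @param bg,fg Background/foreground gray levels (16-bit). Defaults 500, 3000.
#' @param noise_sd Gaussian read-noise SD in gray levels. Default 50.
#' @param seed Optional RNG seed.
#' @return A list with `gray` (integer matrix), `labels` (integer matrix),
#'   `truth` (tibble: `cell_id`, `x_um`, `y_um`, `orientation`,
#'   `aspect_ratio`, `area_um2`) and `pixel_size`.
#' @export
#' @examples
#' fld <- render_cell_field(9, shape_params(aspect_ratio = 2), seed = 1)
#' dim(fld$gray)
render_cell_field <- function(n_cells, shape, pixel_size = 0.5,
                              bg = 500, fg = 3000, noise_sd = 50, seed = NULL) {
  stopifnot(inherits(shape, "shape_params"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) abort("`n_cells` must be >= 1.")
  ax <- ellipse_axes(shape)
  major_full <- 2 * ax["a"]
  spacing <- 2.4 * major_full          # centres >= 2 major axes apart after jitter
  ngrid <- ceiling(sqrt(n_cells))
  side <- spacing * ngrid + major_full
  npx <- ceiling(side / pixel_size) + 1L

  with_seed_if(seed, {
    gx <- ((seq_len(ngrid) - 0.5) * spacing) + major_full / 2
    centres <- expand.grid(x = gx, y = gx)[seq_len(n_cells), ]
    jit <- (spacing - 2 * major_full) / 2
    centres$x <- centres$x + stats::runif(n_cells, -jit, jit)
    centres$y <- centres$y + stats::runif(n_cells, -jit, jit)
    angles <- stats::runif(n_cells, -pi / 2, pi / 2)
    labels <- matrix(0L, npx, npx)
    gray <- matrix(bg, npx, npx)
    for (i in seq_len(n_cells)) {
      drawn <- draw_ellipse(labels, gray, centres$x[i], centres$y[i],
                            ax["a"], ax["b"], angles[i], i, pixel_size,
                            fg, shape$boundary_noise)
      labels <- drawn$labels; gray <- drawn$gray
    }
    list(
      gray = finish_gray(gray, noise_sd),
      labels = labels,
      truth = tibble(cell_id = seq_len(n_cells), x_um = centres$x,
                     y_um = centres$y, orientation = angles,
                     aspect_ratio = shape$aspect_ratio, area_um2 = shape$area),
      pixel_size = pixel_size
    )
  })
}

#' Render a time-lapse stack from simulated tracks
#'
#' For each frame, each cell is drawn as a filled rotated ellipse of the
#' ground-truth area and aspect ratio. Orientation follows the shape's
#' `orientation_mode`: the instantaneous movement direction
#' (`gradient_aligned`), a fixed uniform-random angle per cell (`random`),
#' or a fresh uniform angle per frame (`isotropic`). The label stack carries
#' one unique integer per track; the grayscale stack adds Gaussian noise.
#'
#' @param tracks A track tibble ([simulate_tracks()] output).
#' @param shape A [shape_params()] shared by all tracks, or a list of one
#'   per track (named or in `track_id` order).
#' @param config The [assay_config()] the tracks were simulated with.
#' @param bg,fg,noise_sd Gray levels and read noise as in
#'   [render_cell_field()].
#' @param seed Optional RNG seed.
#' @return A list with `labels` and `gray`: lists of integer matrices, one
#'   per frame (rows = y, cols = x), plus `pixel_size`.
#' @export
render_frames <- function(tracks, shape, config, bg = 500, fg = 3000,
                          noise_sd = 50, seed = NULL) {
  stopifnot(inherits(config, "assay_config"))
  ps <- config$pixel_size
  nr <- ceiling(config$geometry$width / ps) + 1L
  nc <- ceiling(config$field_length / ps) + 1L
  ids <- sort(unique(tracks$track_id))
  shapes <- if (inherits(shape, "shape_params")) {
    stats::setNames(rep(list(shape), length(ids)), ids)
  } else {
    stats::setNames(shape, if (is.null(names(shape))) ids else names(shape))
  }
  frames <- sort(unique(tracks$frame))
  ax_too_big <- vapply(shapes, function(s) 2 * ellipse_axes(s)["a"], 0)
  if (any(ax_too_big > min(config$geometry$width, config$field_length))) {
    abort("A cell's major axis exceeds the imaged field.")
  }

  with_seed_if(seed, {
    fixed_angle <- stats::setNames(stats::runif(length(ids), -pi / 2, pi / 2), ids)
    labels_out <- vector("list", length(frames))
    gray_out <- vector("list", length(frames))
    trk <- tracks[order(tracks$track_id, tracks$frame), ]
    by_frame <- split(trk, trk$frame)
    # previous positions for movement direction
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      cur <- by_frame[[as.character(f)]]
      labels <- matrix(0L, nr, nc)
      gray <- matrix(bg, nr, nc)
      prev <- if (fi > 1) by_frame[[as.character(frames[fi - 1])]] else NULL
      for (j in seq_len(nrow(cur))) {
        id <- cur$track_id[j]
        s <- shapes[[as.character(id)]]
        axx <- ellipse_axes(s)
        ang <- switch(s$orientation_mode,
          gradient_aligned = {
            if (!is.null(prev) && id %in% prev$track_id) {
              k <- match(id, prev$track_id)
              atan2(cur$y_um[j] - prev$y_um[k], cur$x_um[j] - prev$x_um[k])
            } else {
              atan2(config$gradient_axis[2], config$gradient_axis[1])
            }
          },
          random = fixed_angle[[as.character(id)]],
          isotropic = stats::runif(1, -pi / 2, pi / 2)
        )
        drawn <- draw_ellipse(labels, gray, cur$x_um[j], cur$y_um[j],
                              axx["a"], axx["b"], ang, as.integer(id), ps,
                              fg, s$boundary_noise)
        labels <- drawn$labels; gray <- drawn$gray
      }
      labels_out[[fi]] <- labels
      gray_out[[fi]] <- finish_gray(gray, noise_sd)
    }
    list(labels = labels_out, gray = gray_out, pixel_size = ps)
  })
}
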