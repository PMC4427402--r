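#' Channel geometry of the migration channel
#'
#' The migration channel of the microfluidic device is a straight channel;
#' the cross-flow axis `y` spans `[0, width]` with the chemoattractant source
#' stream flowing along the wall at `y = 0`.
#'
#' @param width Channel width in µm (cross-flow axis). Default 350.
#' @param height Channel height in µm. Default 100.
#' @param length_downstream Channel length along the flow axis in µm.
#'
#' @return A list of class `channel_geometry`.
#' @export
#' @examples
#' channel_geometry()
channel_geometry <- function(width = 350, height = 100, length_downstream = 20000) {
  check_number(width, "width", positive = TRUE)
  check_number(height, "height", positive = TRUE)
  check_number(length_downstream, "length_downstream", positive = TRUE)
  structure(
    list(width = width, height = height, length_downstream = length_downstream),
    class = "channel_geometry"
  )
}

#' Assay acquisition configuration
#'
#' Describes the imaging of a chemotaxis experiment: frame interval, number of
#' frames, pixel size, the imaged field and the gradient axis. The gradient
#' axis is the in-plane unit vector pointing up-gradient, i.e. from the sink
#' wall toward the chemoattractant-source wall; with the source stream at
#' `y = 0` this is `c(0, -1)`.
#'
#' @param geometry A [channel_geometry()].
#' @param frame_interval Time between frames in seconds. Default 10.
#' @param n_frames Number of frames. Default 121 (120 steps of 10 s = 20 min).
#' @param pixel_size Pixel size in µm/pixel. Default 1.
#' @param gradient_axis Length-2 unit vector pointing up-gradient.
#' @param field_length Along-flow extent of the imaged region in µm.
#'
#' @return A list of class `assay_config`.
#' @export
#' @examples
#' cfg <- assay_config()
#' cfg$n_frames
assay_config <- function(geometry = channel_geometry(),
                         frame_interval = 10,
                         n_frames = 121,
                         pixel_size = 1,
                         gradient_axis = c(0, -1),
                         field_length = 350) {
  stopifnot(inherits(geometry, "channel_geometry"))
  check_number(frame_interval, "frame_interval", positive = TRUE)
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  check_number(field_length, "field_length", positive = TRUE)
  structure(
    list(
      geometry = geometry,
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      pixel_size = pixel_size,
      gradient_axis = unit_vector(gradient_axis),
      field_length = field_length
    ),
    class = "assay_config"
  )
}

#' Ground-truth motility parameters for the walk simulator
#'
#' Parameterizes the biased random walk used to emulate migrating cells:
#' step directions are von Mises distributed about the bias direction with
#' concentration `kappa` (0 = unbiased, isotropic), per-step speeds follow a
#' Gamma law with mean `mean_step_speed` and shape `speed_shape`
#' (`Inf` = constant speed), and `persistence` optionally blends each step's
#' mean direction with the previous step's direction.
#'
#' @param kappa Directional concentration, >= 0. `Inf` gives straight motion.
#' @param mean_step_speed Mean step speed in µm/s. Default 0.15 (typical of
#'   the per-subject speeds in the packaged subject table).
#' @param speed_shape Gamma shape of the speed law; larger = less dispersed.
#' @param persistence Direction correlation in `[0, 1)`. Default 0; the
#'   Bessel-ratio calibration assumes 0.
#'
#' @return A list of class `motility_params`.
#' @export
motility_params <- function(kappa = 0, mean_step_speed = 0.15,
                            speed_shape = 4, persistence = 0) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  check_number(mean_step_speed, "mean_step_speed", positive = TRUE)
  check_number(speed_shape, "speed_shape", positive = TRUE)
  if (persistence < 0 || persistence >= 1) abort("`persistence` must be in [0, 1).")
  structure(
    list(kappa = kappa, mean_step_speed = mean_step_speed,
         speed_shape = speed_shape, persistence = persistence),
    class = "motility_params"
  )
}

#' Ground-truth shape parameters for rendered cells
#'
#' @param area Cell area in µm². Default 150 (neutrophil scale).
#' @param aspect_ratio True major/minor axis ratio, >= 1.
#' @param orientation_mode One of `"gradient_aligned"` (major axis along the
#'   instantaneous movement direction), `"random"` (fixed uniform-random
#'   orientation per cell) or `"isotropic"` (re-drawn uniform orientation per
#'   frame, no persistent polarity).
#' @param boundary_noise Relative boundary raggedness, >= 0. Default 0.
#'
#' @return A list of class `shape_params`.
#' @export
shape_params <- function(area = 150, aspect_ratio = 1.5,
                         orientation_mode = c("gradient_aligned", "random", "isotropic"),
                         boundary_noise = 0) {
  check_number(area, "area", positive = TRUE)
  if (aspect_ratio < 1) abort("`aspect_ratio` must be >= 1.")
  check_number(boundary_noise, "boundary_noise", nonneg = TRUE)
  orientation_mode <- match.arg(orientation_mode)
  structure(
    list(area = area, aspect_ratio = aspect_ratio,
         orientation_mode = orientation_mode, boundary_noise = boundary_noise),
    class = "shape_params"
  )
}

#' Read / write a flat key-value configuration file
#'
#' The on-disk configuration format is `key = value`, one per line, `#`
#' comments allowed. Unknown keys are rejected.
#'
#' @param path File path.
#' @param defaults Named list of defaults; keys not in `defaults` error.
#' @return `read_config()` returns a named list; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path, defaults) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("Malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) abort(sprintf("Unknown config key: '%s'", key))
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(format(v), collapse = " "), "")),
             path)
  invisible(path)
}
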