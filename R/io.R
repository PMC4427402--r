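#' Write / read the track table dialect
#'
#' Tracks are exchanged as UTF-8 CSV with '.' decimal and columns
#' `track_id, frame, time_s, x_um, y_um, condition` (plus `subject_id` when
#' present). The gradient axis is recorded in a `#`-comment header line so
#' measured and simulated tracks stay interchangeable.
#'
#' @param tracks A track tibble.
#' @param path File path.
#' @param gradient_axis Length-2 unit vector stored in the header comment.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns the track tibble with the axis in attribute
#'   `"gradient_axis"`.
#' @export
write_tracks <- function(tracks, path, gradient_axis = c(0, -1)) {
  g <- unit_vector(gradient_axis)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# gradient_axis: %.10g %.10g", g[1], g[2]), con)
  close(con)
  readr::write_csv(tracks, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  hdr <- readLines(path, n = 1)
  axis <- c(0, -1)
  if (grepl("^# gradient_axis:", hdr)) {
    axis <- as.numeric(strsplit(trimws(sub("^# gradient_axis:", "", hdr)),
                                "\\s+")[[1]])
  }
  tr <- suppressWarnings(readr::read_csv(path, comment = "#",
                                         show_col_types = FALSE,
                                         progress = FALSE))
  probs <- readr::problems(tr)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed track CSV '%s' at row(s): %s", path,
                  paste(unique(probs$row), collapse = ", ")))
  }
  if (nrow(tr) == 0) abort(sprintf("Track file '%s' has a header but no rows.", path))
  need <- c("track_id", "frame", "time_s", "x_um", "y_um")
  if (!all(need %in% names(tr))) {
    abort(sprintf("Track file '%s' is missing columns: %s", path,
                  paste(setdiff(need, names(tr)), collapse = ", ")))
  }
  attr(tr, "gradient_axis") <- unit_vector(axis)
  tr
}

#' Export an image matrix as plain-text TSV
#'
#' Lightweight stand-in for binary image formats: one integer per pixel,
#' tab-separated, row per line.
#'
#' @param img Integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_txt <- function(img, path) {
  utils::write.table(img, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_txt
#' @export
read_image_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t"))
}
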