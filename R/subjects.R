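#' Read a subject table (clinical descriptors + chemotaxis measurements)
#'
#' Reads the per-subject CSV dialect used throughout the package:
#' `subject_id, group, age, sex, FVC_L, FEV1_L, FEV1_FVC_pct, ci_mean,
#' ci_sem, speed_mean_um_s, speed_sem_um_s`, with `NA` for missing
#' spirometry (healthy controls were not tested). The default path is the
#' packaged 10-subject table (5 COPD patients, 5 healthy controls) of
#' measured per-subject chemotactic indices, speeds and spirometry.
#'
#' @param path CSV path; `NULL` (default) loads the packaged table.
#' @return A tibble with the columns above (`fev1_fvc_pct` renamed from
#'   `FEV1_FVC_pct`), validated: `0 < FEV1 <= FVC` where present and
#'   `ci_mean` in `[-1, 1]`.
#' @export
#' @examples
#' tb <- read_subject_table()
#' dplyr::count(tb, group)
read_subject_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1.csv", package = "chemotaxr",
                        mustWork = TRUE)
  }
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "group", "age", "sex", "FVC_L", "FEV1_L",
            "FEV1_FVC_pct", "ci_mean", "ci_sem", "speed_mean_um_s",
            "speed_sem_um_s")
  if (!all(need %in% names(tb))) {
    abort(sprintf("Subject table must have columns: %s",
                  paste(setdiff(need, names(tb)), collapse = ", ")))
  }
  if (!all(tb$group %in% c("COPD", "control"))) {
    abort("`group` must be 'COPD' or 'control'.")
  }
  both <- !is.na(tb$FEV1_L) & !is.na(tb$FVC_L)
  if (any(tb$FEV1_L[both] <= 0 | tb$FEV1_L[both] > tb$FVC_L[both])) {
    abort("Spirometry must satisfy 0 < FEV1 <= FVC.")
  }
  if (any(abs(tb$ci_mean) > 1)) abort("`ci_mean` must be in [-1, 1].")
  dplyr::rename(tb, fev1_fvc_pct = "FEV1_FVC_pct")
}
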