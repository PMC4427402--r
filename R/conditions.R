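#' Describe a chemoattractant source
#'
#' @param name Label, e.g. `"fMLP"`, `"IL-8"`, `"COPD sputum"`.
#' @param class `"terminal"` (bacterial end-target peptides such as fMLP) or
#'   `"intermediate"` (host chemokines such as IL-8, and sputum, whose
#'   activity is IL-8-like).
#' @param potency Chemotactic potency expressed as the asymptotic
#'   chemotactic index the attractant would induce alone, in `[0, 1)`.
#' @return A list of class `attractant`.
#' @export
attractant <- function(name, class = c("intermediate", "terminal"), potency = 0.3) {
  class <- match.arg(class)
  if (potency < 0 || potency >= 1) abort("`potency` must be in [0, 1).")
  structure(list(name = name, class = class, potency = potency),
            class = "attractant")
}

#' Specify an assay condition (single, competing, or uniform field)
#'
#' Encodes the phenomenology of competing gradients: a terminal
#' chemoattractant dominates an intermediate one regardless of potency, and
#' within a class the higher-potency source dominates. The losing gradient
#' attenuates the net bias in proportion to its relative potency. Uniform
#' fields (`uniform = TRUE`) carry no directional cue at all
#' (`effective_kappa = 0`) but still set the morphology.
#'
#' @param label Condition name.
#' @param top_attractant,bottom_attractant Optional [attractant()]s at the
#'   two walls. `bias_sign` is +1 when the dominant source is the top one.
#' @param shape A [shape_params()] for the condition's cell morphology.
#' @param uniform If `TRUE`, the attractant is present everywhere and no
#'   gradient exists.
#' @return A list of class `condition_spec` with fields `label`,
#'   `effective_kappa`, `bias_sign`, `shape`, `dominant`.
#' @export
#' @examples
#' cs <- condition_spec("fMLP100 vs IL8",
#'   top_attractant = attractant("fMLP", "terminal", 0.45),
#'   bottom_attractant = attractant("IL-8", "intermediate", 0.35))
#' cs$bias_sign  # +1: fMLP (terminal) dominates
condition_spec <- function(label, top_attractant = NULL, bottom_attractant = NULL,
                           shape = shape_params(), uniform = FALSE) {
  stopifnot(inherits(shape, "shape_params"))
  rank_of <- function(a) if (is.null(a)) -Inf else
    (a$potency + if (a$class == "terminal") 10 else 0)
  r_top <- rank_of(top_attractant); r_bot <- rank_of(bottom_attractant)
  if (uniform || (is.null(top_attractant) && is.null(bottom_attractant))) {
    eff_ci <- 0; sign <- 0; dom <- NULL
  } else {
    if (r_top >= r_bot) {
      dom <- top_attractant; sub <- bottom_attractant; sign <- 1
    } else {
      dom <- bottom_attractant; sub <- top_attractant; sign <- -1
    }
    # losing gradient attenuates the winner's bias by up to half
    atten <- if (is.null(sub)) 0 else 0.5 * min(1, sub$potency / max(dom$potency, 1e-9))
    eff_ci <- dom$potency * (1 - atten)
  }
  structure(
    list(label = label, top_attractant = top_attractant,
         bottom_attractant = bottom_attractant,
         effective_kappa = if (eff_ci > 0) calibrate_kappa(eff_ci) else 0,
         bias_sign = sign, shape = shape,
         dominant = if (is.null(dom)) NA_character_ else dom$name),
    class = "condition_spec"
  )
}

#' Ground-truth aspect ratios of the uniform-field conditions
#'
#' The per-condition mean aspect ratios measured at the end of the
#' migration experiment in uniform (gradient-free) chemoattractant fields
#' and the medium control, used as calibration targets for the synthetic
#' shape generator: uniform fMLP 1.19, uniform IL-8 2.16, medium 1.17,
#' uniform COPD sputum 1.58, uniform control sputum 1.46.
#'
#' @return A tibble with columns `condition`, `aspect_ratio`,
#'   `orientation_mode`.
#' @export
uniform_field_shapes <- function() {
  tibble(
    condition = c("uniform_fmlp", "uniform_il8", "medium",
                  "uniform_copd_sputum", "uniform_control_sputum"),
    aspect_ratio = c(1.19, 2.16, 1.17, 1.58, 1.46),
    orientation_mode = c("random", "random", "isotropic", "random", "random")
  )
}
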