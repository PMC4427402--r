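---
title: "Quantifying neutrophil chemotaxis in microfluidic gradient channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neutrophil chemotaxis in microfluidic gradient channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxr)
library(dplyr)
```

## The measurement problem

Neutrophils are recruited into inflamed airways by chemoattractant
gradients; in chronic obstructive pulmonary disease (COPD) the sputum of
patients carries elevated chemokines (notably IL-8) and induces stronger
directed migration than sputum from healthy donors. A microfluidic co-flow
channel makes this measurable at the single-cell level: two streams — one
carrying the chemoattractant (recombinant IL-8 or fMLP, or diluted sputum
supernatant), one plain medium — merge into a 350 µm × 100 µm migration
channel, and cross-channel diffusion establishes a stable gradient. Cells
seeded on the channel floor are imaged every 10 s for 15–20 min and their
trajectories are scored by two statistics:

* the **chemotactic index** (C.I.): net displacement along the gradient
  axis divided by total path length, in `[-1, 1]`; positive values mean net
  movement toward the source, 1 is a perfectly straight run;
* the **migration speed**: total path length divided by the track's
  duration (µm/s).

Cell polarization is scored morphometrically as the **aspect ratio** of the
moment-equivalent ellipse of the segmented cell outline.

No raw image data from such experiments is distributed with this package.
Instead, every analysis stage is exercised against a *synthetic assay*
whose ground truth is known exactly, plus one measured per-subject table
(5 COPD patients, 5 healthy controls: spirometry, C.I. ± SEM,
speed ± SEM) that drives the cohort-level statistics.

## Gradient model

The cross-channel profile is modeled as 1-D diffusion of an initial
concentration step (source half at `c0`, sink half at 0) for an effective
mixing time `tau = downstream_distance / mean_flow_speed`, with no-flux
walls. Short times use an image-source `erf` series over the even-periodic
extension of the step; long times switch to the Fourier cosine
eigenfunction series (`s = sqrt(D * tau) >= width/4`), each truncated at
1e-12. This guarantees the physical invariants that stand in for the
(qualitative) published calibration: the spatial mean is 0.5 (mass
conservation), `c(y) + c(width - y) = c0` (antisymmetry), and the profile
flattens monotonically with mixing time.

The channel height and Taylor dispersion are deliberately ignored — only
the cross-channel fluorescence profile is characterized experimentally —
and the pressure-balance hydraulics of the real device is represented only
by the assumption of equal inlet flows. The flow speed is not reported for
the device, so it is an explicit parameter (default 500 µm/s, a typical
scale for pump-free devices of this geometry) used in examples only; all
gradient tests are property-based rather than value-based.
`establishment_time()` models the start-up transient as the advected front
(with axial diffusive spreading) multiplying the steady profile; it is
bounded below by the advection time and decreases with tolerance.

## Synthetic assay: the stated world

`simulate_tracks()` draws biased random walks:

* step directions are von Mises about the bias direction with
  concentration `kappa` (Best–Fisher sampler); `kappa = 0` is isotropic;
* step lengths are `speed * frame_interval`, speeds Gamma with mean
  `mean_step_speed` and shape `speed_shape` (4 by default; `Inf` gives
  constant speed), independent of direction;
* positions reflect specularly at the channel walls;
* an optional `persistence` blends each step's mean direction with the
  previous direction.

The von Mises choice is what makes the simulator *calibratable*: with
i.i.d. directions and direction-independent speeds, the C.I. of a long
track converges to the Bessel-function ratio `I1(kappa)/I0(kappa)`, so
`calibrate_kappa()` can invert any target C.I. in `[0, 1)` exactly
(bisection to 1e-8). Persistence breaks the closed form and is therefore
excluded from calibration — with `persistence > 0` the realized C.I.
exceeds the nominal target, which is the documented bias. Wall reflections
also attenuate the realized C.I. when the drift length approaches the
channel width; calibration-recovery checks therefore use a wide-channel
configuration (4 mm) in which reflections are negligible, while
condition-level simulations keep the realistic 350 µm width.

Defaults mirror the measured assay: 10 s frames, 121 frames (120 steps =
20 min), mean step speed 0.15 µm/s (the scale of the measured per-subject
speeds), 350 µm channel. The gradient axis is stored in the configuration
as a unit vector pointing from the sink wall toward the source wall
(`c(0, -1)` with the source stream at `y = 0`), and the C.I. is *signed*
along that axis, so a condition with the dominant source at the opposite
wall produces negative indices.

Competing-gradient conditions are not modeled mechanistically. A
`condition_spec()` applies the observed dominance phenomenology: a
terminal attractant (fMLP-like) dominates an intermediate one (IL-8-like,
sputum) regardless of potency; within a class the higher potency wins; and
the losing gradient attenuates the winner's net bias by up to half in
proportion to relative potency, which reproduces the dose-dependence of
fMLP dominance. Potencies are expressed directly as the asymptotic C.I.
the attractant would induce alone. Uniform fields carry no directional cue
(`kappa = 0`) but still set the morphology.

Rendered cells are filled rotated ellipses of the ground-truth area
(150 µm², neutrophil scale) and aspect ratio, with Gaussian read noise
(defaults: background 500, foreground 3000, noise SD 50 on a 16-bit
scale). Orientation is the instantaneous movement direction
(`gradient_aligned`), a fixed random angle per cell (`random`, used for
uniform fields where cells polarize in random directions), or re-drawn per
frame (`isotropic`, the unpolarized medium control). Static fields place
cells on a jittered grid whose spacing keeps centres at least two major
axes apart, so segmentation is unambiguous by construction — a green
recovery test therefore establishes the correctness of the measurement
loop, *not* robustness to touching cells, debris, or uneven illumination,
none of which the generator emulates. Frames live in memory as integer
matrices with a plain-text export; no binary image format is written.

`generate_cohort()` builds whole synthetic cohorts: COPD-like subjects
draw FEV1/FVC uniformly on the measured range (35–75, ×100%) and receive a
target C.I. from a *decreasing* linear map plus Gaussian noise
(SD 0.03 by default); the map's slope is set so a uniform FEV1/FVC induces
the measured COPD C.I. spread (SD 0.097 about mean 0.39). Controls draw
C.I. from the measured control distribution (0.22 ± 0.062) and carry no
spirometry, like the measured table. Per-subject speeds are drawn
independently of C.I. (0.158 vs 0.221 µm/s group means, SD 0.05), because
the measured cohort shows no C.I.–speed correlation. Each subject's
`kappa` comes from `calibrate_kappa()`, ≥ 50 tracks are simulated per
subject (mirroring the ≥ 50 cells scored per experiment), and every ground
truth is stored next to the generated data. All randomness flows from one
root seed through fixed derived streams, so any stage is independently
reproducible and a cohort export is byte-identical across runs.

One honest caveat: with the measured group means/SDs at n = 5 + 5, the
closed-form power of the pooled t test is ≈ 0.79, so a single small cohort
replicate can fail to reach significance even though the group difference
is real; the test suite asserts the rejection rate well above the 0.05
baseline rather than near-certain rejection.

## Tracking

Detection is exact in label mode and, for grayscale frames, uses a global
Otsu threshold (256-bin between-class variance), hole filling (background
components not touching the border), removal of components below
`min_area` (default 20 µm²), and component centroids; connected components
are labelled by a batched flood fill. Linking is greedy globally-nearest
pair per frame transition with a hard displacement gate (default
`4 * mean_step_speed * frame_interval`, covering the Gamma speed tail),
gap closing up to `max_gap` frames, and a minimum track length (default
10 frames) before metrics. Ties are broken by distance then lexicographic
centroid order, so the linker is deterministic and invariant to detection
order. Greedy assignment is *adequate under the generator's separation
guarantee* and exact there by test; it is a documented limitation for
dense scenes, where optimal assignment or motion models would be needed.

## Morphometry

`fit_ellipse()` computes the second-order central moments of the filled
pixel region and reports the moment-equivalent ellipse — the same
convention Fiji's "fit ellipse" uses — with full axes `4 * sqrt(lambda)`
and aspect ratio `sqrt(lambda1/lambda2)`, which is free of any axis-scale
convention. No 1/12-pixel variance correction is applied, matching the
common regionprops convention; at the default 0.5 µm pixel size the
discretization bias on a 150 µm² cell is well inside the 5% recovery
tolerance. Regions thinner than the moment floor (`lambda2 ~ 0`) and
regions under 5 pixels are flagged degenerate rather than measured. The
measurement frame defaults to the last of the sequence (end of the
migration experiment), exposed as a parameter.

## Cohort statistics

Group comparisons use the pooled-variance two-sided Student t test (the
study's stated test; Welch is behind a flag), ANOVA for ≥ 3 groups, and
ordinary least squares for the C.I.–spirometry and C.I.–speed relations,
all two-sided at alpha 0.05 with no multiple-testing correction (none is
applied in the source analysis). The published exclusion of one COPD
patient from the spirometry correlation is operationalized as an
exhaustive `leave_one_out_scan()`: every n−1 subset is refit and ranked by
r², which both reproduces the published 4-subject fit (r² ≈ 0.948 ≥ 0.93,
negative slope, excluding the youngest patient — who also has low FEV1/FVC
and low C.I.) and reports the full scan instead of a by-inspection choice.
Whether the published R² of 0.93 was computed from unrounded per-subject
values is unknowable from the printed table; recomputation from the
rounded values gives slightly more, so the acceptance check is a ≥ bound.
SEMs are over cells (tracks) by default, matching the magnitude of the
printed per-subject SEMs; per-experiment layering is possible by grouping
but is not the default.

## Numerical choices

* Gradient series truncation 1e-12; series switch at `sqrt(D tau) = w/4`.
* `calibrate_kappa()` bisection tolerance 1e-8 on the C.I. scale.
* Degenerate guards: stationary tracks get `NA` C.I. and are excluded
  from aggregation with a count; constant groups give `t = 0, p = 1`
  (equal means) rather than an error; zero-variance regressions report
  `r² = 0`.
* Seeds: one root seed; derived streams via a fixed affine map modulo
  2^31 − 19.
* Pixel centres sit at 0-based integer coordinates times the pixel size;
  the pixel→µm conversion happens at detection and nowhere else.

## What the packaged subject table supports

The packaged 10-subject table carries the *measured* per-subject
statistics, so the cohort-level findings — COPD C.I. significantly higher
than control (pooled t = 3.33, df = 8, p = 0.010), no C.I.–speed
correlation, and the negative C.I.–FEV1/FVC relation in 4 of 5 patients —
are recomputed, not asserted. Cell-level claims cannot be regenerated from
published material (no raw images are deposited); they are validated as
parameter-recovery loops on the synthetic assay instead: C.I. recovery at
the calibrated `kappa`, 2% speed recovery, 5% aspect-ratio recovery at the
five uniform-field ground truths (fMLP 1.19, IL-8 2.16, medium 1.17, COPD
sputum 1.58, control sputum 1.46).

## Known limitations

* The walk model is phenomenological; it makes no claim about receptor
  signaling, and `persistence` is excluded from calibration.
* The renderer draws non-touching ellipses; segmentation robustness on
  real DIC images is out of scope.
* Greedy linking assumes separated cells (guaranteed by the generator).
* The competing-gradient dominance rule is a hard-coded phenomenology
  with a single attenuation constant, not a dose–response model.
* n = 5 + 5 cohort statistics are what they are: the leave-one-out scan
  quantifies the fragility of the spirometry correlation rather than
  hiding it.
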