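---
title: "Methods: L3 body composition and toxicity discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: L3 body composition and toxicity discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l3bodycomp)
```

## The problem and the model

Chemotherapy dose is conventionally scaled by body surface area (BSA), but
dose-limiting toxicity (DLT — any dose reduction or discontinuation forced
by toxicity) remains common, and drug distribution plausibly tracks body
*composition* rather than surface area. The quantification substrate is
abdominal CT at the third lumbar vertebra: a single representative
"mid-L3" slice for the classical 2D measurements, and the full stack of
slices spanning L3 for their 3D counterparts. Three compartments are
quantified — skeletal muscle (SM), visceral adipose tissue (VAT) and
subcutaneous adipose tissue (SAT).

The measurement model is deliberately simple and fully unit-explicit:

* Hounsfield conversion: `HU = pixel × rescale_slope + rescale_intercept`,
  per the DICOM rescale attributes carried by each slice.
* Surface area (cm²) on one slice: pixel count × row spacing × column
  spacing / 100. Anisotropic spacing is handled as the row×col product,
  which reduces to the usual square for isotropic scans.
* Radiodensity (HU): arithmetic mean of HU under the compartment mask. An
  empty mask is an *undefined measurement* (`NA`), never an error.
* Height-normalised indices (SMI, VFI, SFI, cm²/m²): area / height². When
  height is unknown the indices are flagged absent and everything else is
  still reported.
* Volume (cm³): Σ over slices of area × thickness / 10, with *per-slice*
  thickness, so mixed-thickness stacks integrate correctly.
* 3D average radiodensity (HU): the **unweighted mean of per-slice mean
  HU** — each slice counts equally regardless of its compartment area.
  A volume-weighted mean is arguably more physical; it is available behind
  `weighted = TRUE` in `avg_radiodensity_3d()` but is off by default,
  because the unweighted form is the convention this analysis follows.
  Slices on which the compartment is absent are skipped, and the number of
  slices used is recorded.

The mid-L3 slice is, in clinical practice, chosen by a trained human
grader. That choice is therefore an explicit, overridable input
(`mid_index`); the reproducible default is the median slice by z position,
taking the lower of the two central slices for even counts.

## Segmentation stand-in

Learned segmentation models for L3 body composition exist but are not
distributable here; the package instead provides (a) a transparent
HU-window + morphology rule and (b) a loader for externally produced masks,
so a model's output can be dropped in without touching any downstream code.

The rule: the body is the largest connected component above
`body_threshold` (default −500 HU), holes filled. SM is the muscle window
(−29..150 HU) inside the body. Because the VAT (−150..−50 HU) and SAT
(−190..−30 HU) windows overlap, adipose tissue is split *geometrically*:
the SM mask is morphologically closed with a disc brush (default radius 3
px) and hole-filled; adipose pixels interior to that closed muscle wall are
VAT, adipose pixels between the wall and the body surface are SAT. Masks
are pairwise disjoint by construction and the rule is deterministic.

Two QC behaviours mirror practice: an all-air raster is rejected as
non-anatomical, and any compartment touching the raster border raises a
`qc_border` flag — a proxy for anatomy extending beyond the field of view,
whose clinical counterpart is a human quality call with no published
numeric threshold.

## Statistics

* Group contrasts use the two-sided Mann–Whitney test: exact enumeration
  when both groups have ≤ 25 observations and no ties, otherwise the
  normal approximation with tie and continuity correction. The returned U
  counts case–control pairs with ties at one half, making
  `U/(n₁n₀)` identically the ROC AUC — a cross-module identity the tests
  enforce.
* Categorical contrasts use the Pearson chi-square with Yates continuity
  correction by default (df = 1). The correction choice is exposed as a
  flag; the default was fixed by verifying which variant reproduces the
  published sex-by-DLT p-value (the corrected one does; the uncorrected
  p is visibly smaller).
* Quartiles use linear interpolation (`quantile` type 7). No convention is
  universal; this one is fixed and recorded in every run log.
* ROC: AUC by midrank placements (equivalently pair counting or the
  trapezoid under the empirical curve — all three are proved equal in the
  tests), confidence intervals by DeLong's nonparametric variance,
  truncated to [0, 1].
* The comparison **direction is fixed per analysis** — by default a lower
  measurement predicts DLT, the orientation natural for muscle volume — and
  is *not* auto-flipped per variable, so a useless variable legitimately
  reports an AUC below 0.5. An `"auto"` mode (median-concordant
  orientation, recorded in the output) exists for exploratory use.
* Optimal cut-point: Youden's J, with deterministic tie-breaks (higher
  specificity, then lower threshold); a maximum-accuracy criterion is
  available behind a flag since "classifies the majority correctly" can be
  read either way. Candidate thresholds are midpoints between adjacent
  distinct observed values plus ±∞; the boundary rule is fixed as
  "value ≥ threshold ⇒ higher class". A fully tied sample yields the lowest
  candidate with a `degenerate` flag.
* Cut-points are evaluated in-sample (the convention of the tables this
  report layout mirrors); no cross-validation is attempted or implied.

## Synthetic data: what it emulates and what it does not

**Phantoms** are nested cylinders — VAT disc, SM ring, SAT annulus, air —
rasterised by pixel-centre membership with Gaussian HU noise, written as
real DICOM files. Geometry defaults (512×512 px, 0.8 mm spacing, 10 slices
× 5 mm; stacks of 4–46 slices of 1–8 mm are representative of clinical L3
coverage) and HU means (SM +40, VAT −91, SAT −104, air −1000) are centred
on typical in-vivo radiodensities. The analytic circle areas and cylinder
volumes are returned alongside, so accuracy statements are against closed
form, with the rasterisation error bounded by 2 × perimeter × pixel area.
Phantoms validate unit handling and the segmentation geometry; they do not
emulate organs, contrast phases, beam hardening or anatomical asymmetry, so
passing them says nothing about segmentation accuracy on real anatomy —
by design, the learned-segmentation question is out of scope.

**Cohorts** draw DLT labels per sex from a Bernoulli prevalence and every
measurement independently from stratum-specific normals. The binormal model
is chosen for testability: the true AUC has the closed form
Φ((μ₀−μ₁)/√(σ₁²+σ₀²)), so AUC recovery is checked against an exact target
(e.g. δ = 0.583 with unit SDs gives Φ(0.583/√2) = 0.66). Default parameters
are the study conditions: 106 women at DLT prevalence 73/106 and 97 men at
47/97, stratum means equal to the published medians and stratum SDs from
the published IQRs via IQR/1.349. The indices (SMI/VFI/SFI), whose
summaries are not published, are scaled from the area parameters by the
sex-median height squared (1.61 m / 1.76 m). Two caveats are intrinsic:
published median/IQR pairs do not pin the AUC (under normality the implied
female SM-volume AUC is ≈ 0.71, not the published 0.66 — which is why AUC
calibration uses the explicit-δ spec), and measurements are drawn
independently, so cross-measurement correlation structure is deliberately
absent. Values are *not* truncated at zero: with these parameters negative
draws are rare and truncation would silently shift the closed-form AUC.

## Numerical and design choices

* DICOM I/O is a small built-in codec for uncompressed little-endian
  single-frame series (explicit VR written; explicit or implicit read), the
  attribute set the pipeline needs, no sequence recursion. It is
  cross-checked against an independent DICOM implementation in the test
  suite. Slice order is defined by z position, never by file enumeration.
* Tube voltage varies across clinical acquisitions (100–140 kVp); no
  kVp-dependent HU correction is applied, matching the source analysis.
* BSA is an input taken from registry data, never computed; no BSA formula
  is implemented.
* Pixel values are stored as signed 16-bit integers; phantom HU means
  should be integers if exact zero-noise radiodensity recovery matters.
* All generators take an explicit integer seed and are byte-deterministic
  given it; every pipeline run writes a log recording the seed and the
  conventions in force (quartile rule, correction, direction, tie-breaks).

## Problem sizes used in the checks

The test suite and acceptance script run entirely on generated data, sized
for sharp yet fast checks: 96–160 px phantoms at 1 mm spacing for geometry
(the full 512 px default is exercised by the analysis drivers), 100-instance
randomized equivalence sweeps for the AUC identities, 500 simulated cohorts
of 40+40 for DeLong coverage (observed ≈ 0.93 at nominal 0.95; the test
asserts the loose ≥ 0.90 bound for stability), and 4 000-patient balanced
cohorts for AUC recovery within ±0.02 of closed form.

## Known limitations

No multivariable modelling, survival analysis or multiple-testing
correction (none is part of this analysis); no automatic L3 localisation,
multi-frame DICOM, compressed transfer syntaxes or non-axial orientations;
the threshold segmentation is a stand-in whose purpose is geometric
correctness and interface fidelity, not anatomical accuracy.
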