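# l3bodycomp

Body-composition analysis at the third lumbar vertebra (L3) for predicting
chemotherapy dose-limiting toxicity (DLT).

Chemotherapy dosing is conventionally scaled by body surface area (BSA), yet
many colorectal-cancer patients still develop toxicities severe enough to
force dose reduction or discontinuation (DLT). CT-derived body composition —
skeletal muscle (SM), visceral adipose tissue (VAT) and subcutaneous adipose
tissue (SAT) quantified on abdominal CT at the L3 level — is a candidate
replacement. This package implements the full quantification and evaluation
pipeline for that question, for imaging scientists and clinical researchers:

* **Image model** — DICOM slice stacks with geometry bookkeeping and the
  Hounsfield conversion `HU = pixel × slope + intercept` (a lightweight
  built-in DICOM codec handles uncompressed little-endian single-frame
  series).
* **Segmentation** — per-slice SM/VAT/SAT masks from a configurable
  HU-window + morphology rule (SM −29..150 HU, VAT −150..−50 HU, SAT
  −190..−30 HU by default; the VAT/SAT split is geometric, via the closed
  muscle-wall contour), or externally produced masks dropped in as lossless
  rasters.
* **Measurements** — the nine 2D mid-L3 quantities per patient: compartment
  surface area `A = n_px · s_row · s_col / 100` (cm²), mean radiodensity
  (HU), and the height-normalised indices `SMI/VFI/SFI = A / h²` (cm²/m²);
  and the six 3D whole-L3 quantities: volume `V = Σ_slices A_k · t_k / 10`
  (cm³, per-slice thickness respected) and average radiodensity (unweighted
  mean of per-slice means).
* **Cohort statistics** — DLT vs no-DLT summaries per sex (median/IQR,
  Mann–Whitney), chi-square (Yates) for categorical contrasts.
* **Discrimination** — per-measurement ROC analysis: AUC = P(random
  case–control pair correctly ordered), DeLong 95% CI, Youden-optimal
  cut-point (J = sensitivity + specificity − 1), and confusion-matrix
  accuracy/sensitivity/specificity of the resulting dichotomisation. The
  comparison direction is fixed per analysis (lower value ⇒ DLT by
  default), never silently auto-flipped.
* **Synthetic data** — nested-cylinder CT phantoms with analytically known
  areas/volumes, and binormal cohorts with closed-form true AUCs
  `AUC = Φ(δ / √(σ₀² + σ₁²))`, so every stage is testable without patient
  data.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data. `Rscript analysis/01_simulate_phantom.R` then
`Rscript analysis/02_measure_phantom.R` prints:

```
Measured vs analytic volumes (cm^3):
  SM     439.55 vs   439.82  (0.06% relative error)
  VAT    566.14 vs   565.49  (0.12% relative error)
  SAT    564.86 vs   565.49  (0.11% relative error)
Mid-L3 SM radiodensity: 39.9 HU (configured mean 40 HU)
```

i.e. the full DICOM → segmentation → measurement chain recovers the
phantom's analytic cylinder volumes to ≈0.1% and the configured muscle
radiodensity to within noise. `Rscript analysis/03_simulate_cohort.R` and
`Rscript analysis/04_evaluate_cohort.R` then simulate a 203-patient cohort
(106 women, 97 men, with the published DLT prevalences and measurement
distributions) and print, per sex, the variables whose AUC beats BSA and
the top variable's cut-point performance, e.g.:

```
Top variable per sex at its optimal cut-point:
  sex          variable   auc cutpoint accuracy sensitivity specificity
1   F     sm_volume_cm3 0.743    334.0    0.736       0.740       0.727
```

Under the generator's truth the strongest discriminator is 3D skeletal
muscle volume in both sexes; at n ≈ 100 per sex the empirical top variable
can differ by sampling, which the reports make visible.

In code, the same pipeline is three calls:

```r
library(l3bodycomp)
ph  <- run_simulate_phantom(phantom_spec(seed = 1), "phantom_dir")
rep <- run_measure("phantom_dir/dicom", height_m = 1.70)
ev  <- run_evaluate(generate_cohort(cohort_sim_spec(seed = 1))$cohort)
```

## Report column contract

Measurement reports use fixed column names (units in the suffix):
`sm_area_cm2`, `sm_density_hu`, `vat_area_cm2`, `vat_density_hu`,
`sat_area_cm2`, `sat_density_hu`, `smi_cm2_m2`, `vfi_cm2_m2`, `sfi_cm2_m2`
(2D, mid-L3) and `sm_volume_cm3`, `sm_density_3d_hu`, `vat_volume_cm3`,
`vat_density_3d_hu`, `sat_volume_cm3`, `sat_density_3d_hu` (3D, whole L3).
Cohort CSVs add `patient_id`, `sex` (`F`/`M`), `age`, `height_m`, `bsa`,
`dlt` (0/1). ROC reports carry
`{sex, variable, auc, ci_low, ci_high, cutpoint, tp, fn, tn, fp, accuracy,
sensitivity, specificity}`.
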