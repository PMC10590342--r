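Package: l3bodycomp
Title: L3 CT Body-Composition Quantification and Toxicity Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CT body composition at the third lumbar vertebra (L3):
    converts raw CT pixel values to Hounsfield units, segments skeletal muscle
    (SM), visceral (VAT) and subcutaneous (SAT) adipose tissue on each slice by
    a configurable Hounsfield-window-plus-morphology rule (or loads externally
    produced masks), and computes the standard two-dimensional mid-L3
    measurements (compartment surface area, radiodensity, and the
    height-normalised indices SMI, VFI, SFI) together with whole-L3
    three-dimensional volumes and average radiodensities. Downstream cohort
    analysis covers group summaries (median/IQR, Mann-Whitney, chi-square) and
    per-measurement ROC discrimination of dose-limiting chemotherapy toxicity:
    AUC with DeLong confidence intervals, Youden optimal cut-points, and
    confusion-matrix performance. Synthetic phantom and cohort generators with
    analytically known ground truth make every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    jsonlite,
    png,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
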