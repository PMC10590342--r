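# Orchestration: the exported run_* functions tie the stages together and
# write the CSV/JSON reports plus a run log recording the conventions in
# force (quartile rule, continuity correction, ROC direction, cut-point
# criterion, seed). The numbered scripts under analysis/ are thin drivers
# over these functions.

.write_run_log <- function(path, stage, seed = NA, extra = list()) {
  log <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("l3bodycomp")),
    seed = seed,
    conventions = list(
      quartiles = "linear interpolation (quantile type 7)",
      chi_square = "Pearson with Yates continuity correction",
      mann_whitney = "exact when both n <= 25 and tie-free, else normal approximation",
      roc_direction = "lower measurement predicts DLT (fixed, not auto-oriented)",
      cutpoint_criterion = "Youden J; ties broken by higher specificity then lower threshold",
      boundary_rule = "value >= threshold classified into the higher class",
      radiodensity_3d = "unweighted mean of per-slice means"
    )
  ), extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a phantom and write its artifacts
#'
#' DICOM series, ground-truth masks, analytic truth side-car and a run log,
#' all deterministic under `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory.
#' @return the [generate_phantom()] result, invisibly.
#' @export
run_simulate_phantom <- function(spec = phantom_spec(), out_dir) {
  phantom <- generate_phantom(spec)
  write_phantom(phantom, out_dir)
  .write_run_log(file.path(out_dir, "run_log.json"), "simulate-phantom",
                 seed = spec$seed)
  invisible(phantom)
}

#' Simulate a cohort and write its artifacts
#'
#' Cohort CSV, true-AUC side-car JSON and a run log, deterministic under
#' `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @param out_dir output directory.
#' @return the [generate_cohort()] result, invisibly.
#' @export
run_simulate_cohort <- function(spec = cohort_sim_spec(), out_dir) {
  sim <- generate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$true_auc, file.path(out_dir, "true_auc.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_run_log(file.path(out_dir, "run_log.json"), "simulate-cohort",
                 seed = spec$seed)
  invisible(sim)
}

#' Measure one patient's series: segmentation + all 15 measurements
#'
#' Reads the DICOM series, obtains per-slice compartment masks (external
#' masks when `masks_dir` is given — the segmentation stage is then skipped
#' — otherwise the HU-window segmentation rule), and computes the 2D and 3D
#' body-composition report.
#'
#' @param dicom_dir directory of DICOM slice files.
#' @param masks_dir optional directory of external mask rasters
#'   (see [load_masks()]).
#' @param height_m patient height (m) for the indices, or `NA`.
#' @param config a [seg_config()] (ignored when masks are supplied).
#' @param mid_index mid-L3 override; `NULL` for the median slice.
#' @param out_dir optional directory for `measurements.csv` + run log.
#' @return one-row measurement tibble (see [measure_patient()]).
#' @export
run_measure <- function(dicom_dir, masks_dir = NULL, height_m = NA_real_,
                        config = seg_config(), mid_index = NULL,
                        out_dir = NULL) {
  series <- read_ct_series(dicom_dir, mid_index = mid_index)
  external <- !is.null(masks_dir)
  masks <- if (external) load_masks(masks_dir, series) else
    segment_series(series, config)
  report <- measure_patient(series, masks, height_m = height_m)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(report), file.path(out_dir, "measurements.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_run_log(file.path(out_dir, "run_log.json"), "measure",
                   extra = list(mask_source = if (external) "external masks"
                                else "HU-window segmentation"))
  }
  report
}

#' Cohort evaluation: summaries, ROC report, top-variable performance
#'
#' Produces the three report layers of the analysis: (1) DLT vs no-DLT
#' group summaries per sex (median/IQR + Mann-Whitney p), (2) the per-sex,
#' per-measurement ROC/AUC/cut-point report, and (3) the confusion-matrix
#' performance of the highest-AUC measurement per sex evaluated at its
#' optimal cut-point.
#'
#' @param cohort cohort tibble or path to a cohort CSV.
#' @param direction,criterion,conf_level passed to [evaluate_all()].
#' @param out_dir optional directory for CSV/JSON reports and the run log.
#' @return list with `summary`, `roc_report`, `top` (one row per sex).
#' @export
run_evaluate <- function(cohort, direction = c("lower", "higher", "auto"),
                         criterion = c("youden", "accuracy"),
                         conf_level = 0.95, out_dir = NULL) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- validate_cohort(cohort)
  summary <- summarize_groups(cohort)
  roc_report <- evaluate_all(cohort, direction = direction,
                             criterion = criterion, conf_level = conf_level)
  top <- dplyr::bind_rows(lapply(split(roc_report, roc_report$sex),
                                 function(b) b[which.max(b$auc), ]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(roc_report, file.path(out_dir, "roc_report.csv"),
                     row.names = FALSE)
    utils::write.csv(top, file.path(out_dir, "top_variable.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary, roc_report = roc_report, top = top),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    .write_run_log(file.path(out_dir, "run_log.json"), "evaluate")
  }
  list(summary = summary, roc_report = roc_report, top = top)
}
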