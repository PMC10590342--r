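# 2D (mid-L3) and 3D (whole-L3) body-composition measurements.
#
# Units: pixel spacing in mm, areas in cm^2, slice thickness in mm, volumes
# in cm^3, radiodensity in HU, height-normalised indices in cm^2/m^2.

#' Compartment surface area on one slice
#'
#' Area = pixel count x row spacing x column spacing, converted mm^2 -> cm^2.
#' Anisotropic spacing is handled as the row x col product.
#'
#' @param mask logical matrix.
#' @param row_spacing_mm,col_spacing_mm pixel spacing, mm.
#' @return area in cm^2 (0 for an empty mask).
#' @export
surface_area <- function(mask, row_spacing_mm, col_spacing_mm = row_spacing_mm) {
  stopifnot(is.matrix(mask), row_spacing_mm > 0, col_spacing_mm > 0)
  sum(mask) * row_spacing_mm * col_spacing_mm / 100
}

#' Compartment radiodensity on one slice
#'
#' Arithmetic mean of the HU values under the mask. An empty mask yields an
#' undefined measurement (`NA`), never an error.
#'
#' @param mask logical matrix.
#' @param hu_image an `hu_image`, or a bare HU matrix of the same shape.
#' @return mean HU, or `NA_real_` for an empty mask.
#' @export
radiodensity_2d <- function(mask, hu_image) {
  values <- if (inherits(hu_image, "hu_image")) hu_image$values else hu_image
  stopifnot(is.matrix(mask), all(dim(mask) == dim(values)))
  if (!any(mask)) return(NA_real_)
  mean(values[mask])
}

#' Height-normalised tissue index
#'
#' `index = area / height^2`, the construction behind SMI, VFI and SFI.
#'
#' @param area_cm2 compartment area, cm^2.
#' @param height_m patient height, m (> 0).
#' @return index in cm^2/m^2.
#' @export
tissue_index <- function(area_cm2, height_m) {
  if (!is.numeric(height_m) || is.na(height_m) || height_m <= 0) {
    stop("height_m must be strictly positive")
  }
  area_cm2 / height_m^2
}

#' Compartment volume across slices
#'
#' Volume = sum over slices of (area_cm2 x thickness_mm / 10); per-slice
#' thickness is respected, so mixed-thickness stacks integrate correctly.
#'
#' @param areas_cm2 numeric vector of per-slice areas, cm^2.
#' @param thickness_mm per-slice thickness, mm (recycled if scalar).
#' @return volume in cm^3.
#' @export
volume_3d <- function(areas_cm2, thickness_mm) {
  stopifnot(length(areas_cm2) >= 1L)
  thickness_mm <- rep_len(thickness_mm, length(areas_cm2))
  stopifnot(all(thickness_mm > 0))
  sum(areas_cm2 * thickness_mm / 10)
}

#' Whole-stack average radiodensity
#'
#' By default the unweighted mean of the per-slice mean HU values — slice
#' means count equally regardless of compartment area on each slice. Slices
#' where the compartment is absent (`NA` slice mean) are skipped. A
#' volume-weighted variant (weights = per-slice area x thickness) is
#' available behind `weighted = TRUE`.
#'
#' @param slice_means per-slice mean HU (may contain `NA`).
#' @param weights optional per-slice weights for the weighted variant.
#' @param weighted use the volume-weighted mean instead of the plain mean of
#'   slice means.
#' @return average HU, or `NA_real_` if every slice is undefined.
#' @export
avg_radiodensity_3d <- function(slice_means, weights = NULL, weighted = FALSE) {
  ok <- !is.na(slice_means)
  if (!any(ok)) return(NA_real_)
  if (weighted) {
    stopifnot(!is.null(weights), length(weights) == length(slice_means))
    sum(slice_means[ok] * weights[ok]) / sum(weights[ok])
  } else {
    mean(slice_means[ok])
  }
}

#' All 15 body-composition measurements for one patient
#'
#' 2D measurements (surface area, radiodensity per compartment, plus SMI,
#' VFI, SFI when height is known) come from the designated mid-L3 slice
#' only; 3D measurements (volume and average radiodensity per compartment)
#' integrate every slice of the series.
#'
#' @param series a [ct_series()].
#' @param masks list of [tissue_mask_set()], one per slice in z order.
#' @param height_m patient height in m, or `NA` — the indices are then
#'   flagged absent (`NA`), everything else is still computed.
#' @return one-row [tibble::tibble] with columns `patient_id`, `n_slices`,
#'   `qc_border`, the nine 2D measurements (`sm_area_cm2`, `sm_density_hu`,
#'   `vat_area_cm2`, `vat_density_hu`, `sat_area_cm2`, `sat_density_hu`,
#'   `smi_cm2_m2`, `vfi_cm2_m2`, `sfi_cm2_m2`) and the six 3D measurements
#'   (`sm_volume_cm3`, `sm_density_3d_hu`, `vat_volume_cm3`,
#'   `vat_density_3d_hu`, `sat_volume_cm3`, `sat_density_3d_hu`).
#' @export
measure_patient <- function(series, masks, height_m = NA_real_) {
  stopifnot(inherits(series, "ct_series"))
  n <- length(series$slices)
  if (length(masks) != n) {
    stop("need one tissue_mask_set per slice (", n, "), got ", length(masks))
  }
  compartments <- c("sm", "vat", "sat")
  per_slice <- lapply(seq_len(n), function(i) {
    sl <- series$slices[[i]]
    hu <- to_hounsfield(sl)
    vapply(compartments, function(comp) {
      m <- masks[[i]][[comp]]
      c(area = surface_area(m, sl$row_spacing_mm, sl$col_spacing_mm),
        density = radiodensity_2d(m, hu),
        thickness = sl$thickness_mm)
    }, numeric(3))
  })

  out <- list(patient_id = series$patient_id, n_slices = n)
  qc <- vapply(masks, function(m) isTRUE(attr(m, "qc_border")), logical(1))
  out$qc_border <- any(qc)

  mid <- per_slice[[series$mid_index]]
  for (comp in compartments) {
    out[[paste0(comp, "_area_cm2")]] <- mid["area", comp]
    out[[paste0(comp, "_density_hu")]] <- mid["density", comp]
  }
  idx_names <- c(sm = "smi_cm2_m2", vat = "vfi_cm2_m2", sat = "sfi_cm2_m2")
  for (comp in compartments) {
    out[[idx_names[[comp]]]] <- if (is.na(height_m)) NA_real_ else
      tissue_index(mid["area", comp], height_m)
  }
  for (comp in compartments) {
    areas <- vapply(per_slice, function(s) s["area", comp], numeric(1))
    dens <- vapply(per_slice, function(s) s["density", comp], numeric(1))
    thick <- vapply(per_slice, function(s) s["thickness", comp], numeric(1))
    out[[paste0(comp, "_volume_cm3")]] <- volume_3d(areas, thick)
    out[[paste0(comp, "_density_3d_hu")]] <- avg_radiodensity_3d(dens)
  }
  tibble::as_tibble(out)
}

#' Names of the 15 body-composition measurement columns
#'
#' The stable column contract of measurement reports and cohort tables:
#' nine 2D measurements followed by six 3D measurements.
#'
#' @return character vector of length 15.
#' @export
measurement_columns <- function() {
  c("sm_area_cm2", "sm_density_hu", "vat_area_cm2", "vat_density_hu",
    "sat_area_cm2", "sat_density_hu", "smi_cm2_m2", "vfi_cm2_m2",
    "sfi_cm2_m2", "sm_volume_cm3", "sm_density_3d_hu", "vat_volume_cm3",
    "vat_density_3d_hu", "sat_volume_cm3", "sat_density_3d_hu")
}
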