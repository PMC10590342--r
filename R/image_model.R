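#' CT slice with acquisition geometry
#'
#' A single axial CT slice: raw integer pixel values plus the metadata needed
#' to convert to Hounsfield units (rescale slope/intercept) and to measure
#' areas and volumes (pixel spacing, slice thickness, z position).
#'
#' @param pixels integer matrix (rows x cols) of raw scanner pixel values.
#' @param rescale_slope,rescale_intercept linear rescale parameters mapping
#'   raw pixel values to Hounsfield units (`HU = pixel * slope + intercept`).
#' @param row_spacing_mm,col_spacing_mm physical size of one pixel, mm.
#' @param thickness_mm slice thickness, mm.
#' @param z_position slice position along the table axis, mm; the stack
#'   ordering key.
#' @param patient_id optional identifier carried through to reports.
#' @return an object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, rescale_slope = 1, rescale_intercept = -1024,
                     row_spacing_mm = 1, col_spacing_mm = row_spacing_mm,
                     thickness_mm = 5, z_position = 0,
                     patient_id = NA_character_) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("pixels must be a non-empty matrix")
  }
  if (!is.numeric(rescale_slope) || rescale_slope == 0) {
    stop("invalid metadata: rescale_slope must be nonzero")
  }
  for (v in c(row_spacing_mm, col_spacing_mm, thickness_mm)) {
    if (!is.numeric(v) || is.na(v) || v <= 0) {
      stop("pixel spacing and slice thickness must be strictly positive")
    }
  }
  structure(
    list(pixels = pixels, rescale_slope = rescale_slope,
         rescale_intercept = rescale_intercept,
         row_spacing_mm = row_spacing_mm, col_spacing_mm = col_spacing_mm,
         thickness_mm = thickness_mm, z_position = z_position,
         patient_id = patient_id),
    class = "ct_slice"
  )
}

#' Ordered stack of CT slices spanning L3
#'
#' Slices are sorted by z position on construction, so the series is invariant
#' to the order in which slice files were enumerated. `mid_index` designates
#' the representative mid-L3 slice used for 2D measurements; in clinical
#' practice this slice is picked by a trained grader, so the index is an
#' explicit, overridable input. The default is the median slice by z position
#' (the lower of the two central slices when the count is even).
#'
#' @param slices list of [ct_slice()] objects (at least one).
#' @param mid_index index of the mid-L3 slice after z-sorting, or `NULL` for
#'   the median-slice default.
#' @param patient_id identifier; defaults to the first slice's.
#' @return an object of class `ct_series`.
#' @export
ct_series <- function(slices, mid_index = NULL, patient_id = NULL) {
  if (!is.list(slices) || length(slices) < 1L ||
      !all(vapply(slices, inherits, logical(1), "ct_slice"))) {
    stop("slices must be a non-empty list of ct_slice objects")
  }
  z <- vapply(slices, function(s) s$z_position, numeric(1))
  if (anyDuplicated(z)) stop("slices must have distinct z positions")
  slices <- slices[order(z)]
  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1L) {
    stop("inconsistent raster shapes across slices: ",
         paste(unique(shapes), collapse = ", "))
  }
  n <- length(slices)
  if (is.null(mid_index)) mid_index <- (n + 1L) %/% 2L
  if (mid_index < 1L || mid_index > n) {
    stop("mid_index must lie in 1..", n)
  }
  if (is.null(patient_id)) patient_id <- slices[[1]]$patient_id
  structure(
    list(slices = slices, mid_index = as.integer(mid_index),
         patient_id = patient_id),
    class = "ct_series"
  )
}

#' @export
length.ct_series <- function(x) length(x$slices)

#' @export
print.ct_series <- function(x, ...) {
  dims <- dim(x$slices[[1]]$pixels)
  cat(sprintf("ct_series '%s': %d slice(s) of %dx%d px, mid-L3 index %d\n",
              x$patient_id, length(x$slices), dims[1], dims[2], x$mid_index))
  invisible(x)
}

#' Convert raw pixel values to Hounsfield units
#'
#' Applies the DICOM linear rescale `HU = pixel * slope + intercept`
#' elementwise, preserving raster shape and copying the slice geometry.
#'
#' @param slice a [ct_slice()].
#' @return an object of class `hu_image`: list with `values` (HU matrix),
#'   `row_spacing_mm`, `col_spacing_mm`, `thickness_mm`.
#' @export
to_hounsfield <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  if (slice$rescale_slope == 0) stop("invalid metadata: rescale_slope is zero")
  structure(
    list(values = slice$pixels * slice$rescale_slope + slice$rescale_intercept,
         row_spacing_mm = slice$row_spacing_mm,
         col_spacing_mm = slice$col_spacing_mm,
         thickness_mm = slice$thickness_mm),
    class = "hu_image"
  )
}

#' Read a DICOM series from a directory
#'
#' Reads every regular file in `path` as a DICOM slice, sorts by z position
#' and assembles a [ct_series()]. Per-file errors name the missing attribute.
#'
#' @param path directory containing one DICOM file per slice.
#' @param mid_index mid-L3 slice override (after z-sorting); `NULL` for the
#'   median-slice default.
#' @return a [ct_series()].
#' @export
read_ct_series <- function(path, mid_index = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no slice files found in ", path)
  slices <- lapply(files, read_dicom_slice)
  ct_series(slices, mid_index = mid_index)
}

#' Write a series as one DICOM file per slice
#'
#' @param series a [ct_series()].
#' @param path output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_ct_series <- function(series, path) {
  stopifnot(inherits(series, "ct_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series$slices))
  for (i in seq_along(series$slices)) {
    paths[i] <- file.path(path, sprintf("slice%03d.dcm", i))
    write_dicom_slice(series$slices[[i]], paths[i], instance_number = i)
  }
  invisible(paths)
}
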