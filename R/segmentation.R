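# Hounsfield-window + morphology segmentation of SM / VAT / SAT.
#
# This is a deliberately simple, fully configurable rule, not a learned
# model: each compartment is selected by its conventional HU window, and the
# visceral/subcutaneous split — the windows overlap — is resolved
# geometrically by the closed muscle-wall contour. Externally produced masks
# (e.g. from a segmentation model) can be supplied instead via load_masks().

#' Segmentation configuration
#'
#' Default HU windows follow the convention used by standard L3
#' body-composition tooling: skeletal muscle -29..150 HU, visceral adipose
#' -150..-50 HU, subcutaneous adipose -190..-30 HU.
#'
#' @param sm_window,vat_window,sat_window numeric length-2 `(low, high)` HU
#'   windows per compartment.
#' @param body_threshold HU above which a pixel may belong to the body; the
#'   body region is the largest connected component above it, holes filled.
#' @param morphology_radius_px radius (pixels) of the disc structuring
#'   element used to close the muscle wall before the inside/outside split.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(sm_window = c(-29, 150),
                       vat_window = c(-150, -50),
                       sat_window = c(-190, -30),
                       body_threshold = -500,
                       morphology_radius_px = 3L) {
  for (w in list(sm_window, vat_window, sat_window)) {
    if (length(w) != 2L || !is.numeric(w) || w[1] >= w[2]) {
      stop("each HU window must be numeric (low, high) with low < high")
    }
  }
  stopifnot(morphology_radius_px >= 1L)
  structure(
    list(sm_window = sm_window, vat_window = vat_window,
         sat_window = sat_window, body_threshold = body_threshold,
         morphology_radius_px = as.integer(morphology_radius_px)),
    class = "seg_config"
  )
}

#' Per-slice binary compartment masks
#'
#' Validates the compartment invariants: identical raster shape and pairwise
#' per-pixel disjointness of SM, VAT and SAT.
#'
#' @param sm,vat,sat logical matrices of identical shape.
#' @return an object of class `tissue_mask_set`.
#' @export
tissue_mask_set <- function(sm, vat, sat) {
  masks <- list(sm = sm, vat = vat, sat = sat)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.matrix(m) || !is.logical(m)) stop(nm, " mask must be a logical matrix")
  }
  if (!all(dim(sm) == dim(vat)) || !all(dim(sm) == dim(sat))) {
    stop("compartment masks must share one raster shape")
  }
  overlap <- sum(sm & vat) + sum(sm & sat) + sum(vat & sat)
  if (overlap > 0L) {
    stop("compartment masks overlap on ", overlap, " pixel(s)")
  }
  structure(masks, class = "tissue_mask_set")
}

.as_binary <- function(img) {
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  m > 0.5
}

.largest_component <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  if (max(lab) < 1L) return(NULL)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Segment one HU slice into SM, VAT and SAT
#'
#' Rule: the body is the largest connected component above
#' `body_threshold`, holes filled. SM is the muscle HU window inside the
#' body. The muscle wall is closed with a disc brush and hole-filled; adipose
#' pixels interior to the wall become VAT, adipose pixels between the wall
#' and the body surface become SAT. Masks are disjoint by construction.
#'
#' @param image an `hu_image` from [to_hounsfield()].
#' @param config a [seg_config()].
#' @return a [tissue_mask_set()] with attribute `qc_border` (`TRUE` when any
#'   compartment touches the raster border, a proxy flag for anatomy
#'   extending beyond the field of view).
#' @export
segment_slice <- function(image, config = seg_config()) {
  stopifnot(inherits(image, "hu_image"), inherits(config, "seg_config"))
  hu <- image$values
  body <- .largest_component(hu > config$body_threshold)
  if (is.null(body)) {
    stop("empty body region: no pixels above body threshold (non-anatomical input)")
  }
  body <- .as_binary(EBImage::fillHull(body * 1))

  in_window <- function(w) hu >= w[1] & hu <= w[2]
  sm <- body & in_window(config$sm_window)

  brush <- EBImage::makeBrush(2L * config$morphology_radius_px + 1L, shape = "disc")
  wall <- .as_binary(EBImage::closing(sm * 1, brush))
  interior <- .as_binary(EBImage::fillHull(wall * 1))

  vat <- body & interior & !sm & in_window(config$vat_window)
  sat <- body & !interior & !sm & in_window(config$sat_window)

  masks <- tissue_mask_set(sm = sm, vat = vat, sat = sat)
  border <- function(m) any(m[1, ]) || any(m[nrow(m), ]) ||
    any(m[, 1]) || any(m[, ncol(m)])
  attr(masks, "qc_border") <- border(sm) || border(vat) || border(sat)
  masks
}

#' Segment every slice of a series
#'
#' @param series a [ct_series()].
#' @param config a [seg_config()].
#' @return list of [tissue_mask_set()], one per slice, in z order.
#' @export
segment_series <- function(series, config = seg_config()) {
  stopifnot(inherits(series, "ct_series"))
  lapply(series$slices, function(s) segment_slice(to_hounsfield(s), config))
}

#' Write compartment masks as lossless PNG rasters
#'
#' One 0/255 grayscale PNG per slice per compartment, named
#' `slice<k>_<compartment>.png`.
#'
#' @param masks list of [tissue_mask_set()] (one per slice).
#' @param path output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_masks <- function(masks, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(masks)) {
    for (comp in c("sm", "vat", "sat")) {
      p <- file.path(path, sprintf("slice%03d_%s.png", i, comp))
      png::writePNG(masks[[i]][[comp]] * 1, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Load externally produced compartment masks
#'
#' Expects the naming convention of [write_masks()]: one lossless raster per
#' slice per compartment. Masks are binarized at 0.5 and validated against
#' the series raster shape and the pairwise-disjointness invariant.
#'
#' @param path directory of mask rasters.
#' @param series the [ct_series()] the masks belong to.
#' @return list of [tissue_mask_set()], one per slice.
#' @export
load_masks <- function(path, series) {
  stopifnot(inherits(series, "ct_series"))
  n <- length(series$slices)
  shape <- dim(series$slices[[1]]$pixels)
  lapply(seq_len(n), function(i) {
    comp <- lapply(c(sm = "sm", vat = "vat", sat = "sat"), function(cname) {
      p <- file.path(path, sprintf("slice%03d_%s.png", i, cname))
      if (!file.exists(p)) stop("missing mask file: ", p)
      m <- png::readPNG(p)
      if (length(dim(m)) > 2L) m <- m[, , 1]
      if (!all(dim(m) == shape)) {
        stop("mask ", p, " shape ", paste(dim(m), collapse = "x"),
             " does not match slice shape ", paste(shape, collapse = "x"))
      }
      m > 0.5
    })
    tissue_mask_set(sm = comp$sm, vat = comp$vat, sat = comp$sat)
  })
}
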