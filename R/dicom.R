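# Lightweight DICOM codec for single-frame axial CT slices.
#
# Scope: uncompressed little-endian transfer syntaxes only (Explicit VR
# "1.2.840.10008.1.2.1" for writing; Explicit or Implicit VR for reading),
# single-frame MONOCHROME2 pixel data, no nested sequences. This covers the
# attributes body-composition analysis needs: PixelData, RescaleSlope,
# RescaleIntercept, PixelSpacing, SliceThickness and a z-ordering attribute.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPLEMENTATION <- "1.2.826.0.1.3680043.9.7484.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tag -> VR lookup for implicit-VR reading (only tags this codec interprets)
.dcm_vr_table <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0010,0020" = "LO", "0018,0050" = "DS", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS", "0020,1041" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW"
)

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.dcm_pad <- function(bytes, pad = as.raw(0x20L)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dcm_str <- function(x, uid = FALSE) {
  .dcm_pad(charToRaw(x), pad = if (uid) as.raw(0L) else as.raw(0x20L))
}

# numeric -> DS string; enough digits for lossless doubles of the magnitudes used
.dcm_ds <- function(x) .dcm_str(paste(formatC(x, format = "g", digits = 10), collapse = "\\"))

.dcm_element <- function(group, element, vr, value) {
  head <- c(.u16le(group), .u16le(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0L, 0L)), .u32le(length(value)), value)
  } else {
    stopifnot(length(value) < 65536L)
    c(head, .u16le(length(value)), value)
  }
}

#' @noRd
#' @param omit character vector of "GGGG,EEEE" tags to leave out (test hook
#'   for exercising missing-attribute error paths)
write_dicom_slice <- function(slice, path, sop_instance_uid = NULL,
                              instance_number = 1L, omit = character()) {
  stopifnot(inherits(slice, "ct_slice"))
  if (is.null(sop_instance_uid)) {
    sop_instance_uid <- paste0(UID_IMPLEMENTATION, ".", instance_number)
  }
  px <- slice$pixels
  if (any(px < -32768 | px > 32767)) {
    stop("pixel values exceed the signed 16-bit range")
  }
  pixel_bytes <- writeBin(as.integer(t(px)), raw(), size = 2L, endian = "little")

  el <- function(tag, vr, value) {
    if (tag %in% omit) return(raw(0))
    ge <- strtoi(strsplit(tag, ",")[[1]], base = 16L)
    .dcm_element(ge[1], ge[2], vr, value)
  }

  meta <- c(
    .dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    .dcm_element(0x0002L, 0x0002L, "UI", .dcm_str(UID_CT_IMAGE_STORAGE, uid = TRUE)),
    .dcm_element(0x0002L, 0x0003L, "UI", .dcm_str(sop_instance_uid, uid = TRUE)),
    .dcm_element(0x0002L, 0x0010L, "UI", .dcm_str(TS_EXPLICIT_LE, uid = TRUE)),
    .dcm_element(0x0002L, 0x0012L, "UI", .dcm_str(UID_IMPLEMENTATION, uid = TRUE))
  )
  body <- c(
    el("0008,0016", "UI", .dcm_str(UID_CT_IMAGE_STORAGE, uid = TRUE)),
    el("0008,0018", "UI", .dcm_str(sop_instance_uid, uid = TRUE)),
    el("0008,0060", "CS", .dcm_str("CT")),
    el("0010,0020", "LO", .dcm_str(slice$patient_id %||% "anonymous")),
    el("0018,0050", "DS", .dcm_ds(slice$thickness_mm)),
    el("0020,0013", "IS", .dcm_str(as.character(instance_number))),
    el("0020,0032", "DS", .dcm_ds(c(0, 0, slice$z_position))),
    el("0020,0037", "DS", .dcm_ds(c(1, 0, 0, 0, 1, 0))),
    el("0020,1041", "DS", .dcm_ds(slice$z_position)),
    el("0028,0002", "US", .u16le(1L)),
    el("0028,0004", "CS", .dcm_str("MONOCHROME2")),
    el("0028,0010", "US", .u16le(nrow(px))),
    el("0028,0011", "US", .u16le(ncol(px))),
    el("0028,0030", "DS", .dcm_ds(c(slice$row_spacing_mm, slice$col_spacing_mm))),
    el("0028,0100", "US", .u16le(16L)),
    el("0028,0101", "US", .u16le(16L)),
    el("0028,0102", "US", .u16le(15L)),
    el("0028,0103", "US", .u16le(1L)),
    el("0028,1052", "DS", .dcm_ds(slice$rescale_intercept)),
    el("0028,1053", "DS", .dcm_ds(slice$rescale_slope)),
    el("7FE0,0010", "OW", pixel_bytes)
  )
  group_len <- .dcm_element(0x0002L, 0x0000L, "UL", .u32le(length(meta)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), group_len, meta, body), con)
  invisible(path)
}

# parse one file into a named list of interpreted attribute values
read_dicom_attributes <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM file (too short): ", path)
  buf <- readBin(path, "raw", n)
  if (rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  u16 <- function(at) readBin(buf[at:(at + 1L)], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(buf[at:(at + 3L)], "integer", size = 4L,
                              endian = "little")
  pos <- 133L
  explicit <- TRUE   # file meta group is always explicit VR
  attrs <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    if (group != 0x0002L && !is.null(attrs[["0002,0010"]])) {
      ts <- attrs[["0002,0010"]]
      explicit <- if (ts == TS_IMPLICIT_LE) FALSE else if (ts == TS_EXPLICIT_LE) TRUE else
        stop("unsupported transfer syntax '", ts, "' in ", path)
      attrs[["0002,0010"]] <- NULL
      attrs[["transfer_syntax"]] <- ts
    }
    tag <- sprintf("%04X,%04X", group, element)
    if (explicit || group == 0x0002L) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% .dcm_long_vrs) {
        len <- u32(pos + 8L); val_at <- pos + 12L
      } else {
        len <- u16(pos + 6L); val_at <- pos + 8L
      }
    } else {
      vr <- .dcm_vr_table[[tag]] %||% "UN"
      len <- u32(pos + 4L); val_at <- pos + 8L
    }
    if (len < 0L || val_at + len - 1L > n) stop("truncated DICOM element ", tag, " in ", path)
    value <- if (len > 0L) buf[val_at:(val_at + len - 1L)] else raw(0)
    attrs[[tag]] <- .dcm_decode(vr, value)
    pos <- val_at + len
  }
  attrs
}

.dcm_decode <- function(vr, bytes) {
  switch(vr,
    DS = as.numeric(strsplit(rawToChar(bytes), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(rawToChar(bytes), "\\", fixed = TRUE)[[1]]),
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    UI = ,
    CS = ,
    LO = ,
    SH = ,
    PN = sub(" +$", "", rawToChar(bytes[bytes != as.raw(0L)])),
    bytes
  )
}

#' Read one CT slice from a DICOM file
#'
#' Supports uncompressed little-endian single-frame files. Raises an error
#' naming the first missing attribute among the ones the body-composition
#' pipeline requires.
#'
#' @param path path to a DICOM file.
#' @return a [ct_slice()] object.
#' @export
read_dicom_slice <- function(path) {
  attrs <- read_dicom_attributes(path)
  need <- c(RescaleSlope = "0028,1053", RescaleIntercept = "0028,1052",
            PixelSpacing = "0028,0030", SliceThickness = "0018,0050",
            Rows = "0028,0010", Columns = "0028,0011", PixelData = "7FE0,0010")
  for (i in seq_along(need)) {
    if (is.null(attrs[[need[[i]]]])) {
      stop("DICOM file ", path, " is missing required attribute ",
           names(need)[i], " (", need[[i]], ")")
    }
  }
  z <- attrs[["0020,0032"]][3] %||% attrs[["0020,1041"]][1] %||%
    as.numeric(attrs[["0020,0013"]][1])
  if (is.null(z) || is.na(z)) {
    stop("DICOM file ", path, " has no z-ordering attribute ",
         "(ImagePositionPatient, SliceLocation or InstanceNumber)")
  }
  rows <- attrs[["0028,0010"]]; cols <- attrs[["0028,0011"]]
  signed <- isTRUE(attrs[["0028,0103"]] == 1L)
  bytes <- attrs[["7FE0,0010"]]
  if (length(bytes) < 2L * rows * cols) {
    stop("DICOM file ", path, " has truncated PixelData")
  }
  vals <- readBin(bytes, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  spacing <- attrs[["0028,0030"]]  # DICOM order: row spacing, column spacing
  ct_slice(
    pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
    rescale_slope = attrs[["0028,1053"]][1],
    rescale_intercept = attrs[["0028,1052"]][1],
    row_spacing_mm = spacing[1],
    col_spacing_mm = spacing[2] %||% spacing[1],
    thickness_mm = attrs[["0018,0050"]][1],
    z_position = z,
    patient_id = attrs[["0010,0020"]] %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
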