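# Minimal single-series DICOM support: uncompressed little-endian CT slices,
# explicit or implicit VR, one file per slice. Covers the tags a quantitative
# CT pipeline needs (geometry, rescale, pixel data); everything else is
# skipped. Axial identity orientation is assumed (non-axial reformats are out
# of scope).

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

dcm_uint <- function(raw) sum(as.double(raw) * 256^(seq_along(raw) - 1))

dcm_tag <- function(raw4) {
  sprintf("%04x%04x", dcm_uint(raw4[1:2]), dcm_uint(raw4[3:4]))
}

# Parse one DICOM file into a list of tag -> raw value (plus decoded fields).
dcm_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  explicit_vrs_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    tag <- dcm_tag(bytes[pos:(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit) {
      if (vr %in% explicit_vrs_long) {
        len <- dcm_uint(bytes[(pos + 8L):(pos + 11L)])
        vpos <- pos + 12L
      } else {
        len <- dcm_uint(bytes[(pos + 6L):(pos + 7L)])
        vpos <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_uint(bytes[(pos + 4L):(pos + 7L)])
      vpos <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported: ", path)
    if (vpos + len - 1L > n) stop("truncated DICOM element ", tag, " in ", path)
    if (len > 0) out[[tag]] <- bytes[vpos:(vpos + len - 1L)]
    else out[[tag]] <- raw(0)
    if (tag == "7fe00010") break # pixel data is last element we need
    pos <- vpos + as.integer(len)
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el), useBytes = TRUE))
}

dcm_ds <- function(el) {
  s <- dcm_str(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el, "integer", n = length(el) / 2L, size = 2L, signed = FALSE,
          endian = "little")
}

# Decode one slice file to list(rows, cols, spacing, position, slope,
# intercept, series_uid, instance, stored) with stored values as a matrix.
dcm_read_slice <- function(path) {
  el <- dcm_parse_file(path)
  rows <- dcm_us(el[["00280010"]])
  cols <- dcm_us(el[["00280011"]])
  if (is.null(rows) || is.null(cols)) stop("not a DICOM image (Rows/Columns missing): ", path)
  bits <- dcm_us(el[["00280100"]])
  if (!is.null(bits) && bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  rep_ <- dcm_us(el[["00280103"]])
  signed <- !is.null(rep_) && rep_ == 1L
  px <- el[["7fe00010"]]
  if (is.null(px)) stop("no pixel data in ", path)
  v <- readBin(px, "integer", n = rows * cols, size = 2L, signed = signed,
               endian = "little")
  stored <- t(matrix(v, nrow = cols, ncol = rows)) # DICOM is row-major
  list(
    rows = rows, cols = cols, stored = stored,
    spacing = dcm_ds(el[["00280030"]]),           # (row mm, col mm)
    thickness = dcm_ds(el[["00180050"]]),
    position = dcm_ds(el[["00200032"]]),          # (x, y, z) mm
    slope = dcm_ds(el[["00281053"]]),
    intercept = dcm_ds(el[["00281052"]]),
    series_uid = dcm_str(el[["0020000e"]]),
    instance = dcm_ds(el[["00200013"]])
  )
}

dcm_pad <- function(s, pad = as.raw(0L)) {
  r <- charToRaw(s)
  if (length(r) %% 2L) r <- c(r, pad)
  r
}

dcm_el_explicit <- function(group, elem, vr, value_raw) {
  hdr <- writeBin(c(group, elem), raw(), size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

dcm_el_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  dcm_el_explicit(group, elem, vr, dcm_pad(s, pad))
}

dcm_el_us <- function(group, elem, v) {
  dcm_el_explicit(group, elem, "US",
                  writeBin(as.integer(v), raw(), size = 2L, endian = "little"))
}

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian CT file per slice with standard
#' geometry and rescale tags (slope 1, intercept -1024; stored values are
#' signed 16-bit `HU + 1024`). Voxel HU must be integers so the series
#' round-trips exactly; non-integer input is rounded with a warning.
#'
#' @param vol a [ct_volume()].
#' @param dir output directory (created if needed).
#' @param series_uid series instance UID; a fixed-root UID derived from
#'   `vol$source_id` by default so rewrites are deterministic.
#' @return Invisibly, the vector of file paths written (one per slice).
#' @export
write_ct_dicom <- function(vol, dir, series_uid = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.3680043.9999.",
                         sum(utf8ToInt(vol$source_id)) %% 100000, ".1")
  hu <- vol$voxels
  if (max(abs(hu - round(hu))) > 0) {
    warning("non-integer HU rounded for DICOM storage")
    hu <- round(hu)
  }
  intercept <- -1024
  paths <- character(vol$slice_count)
  for (k in seq_len(vol$slice_count)) {
    sl <- hu[, , k] - intercept
    z <- vol$origin[3] + (k - 1) * vol$spacing[3]
    ds <- c(
      dcm_el_str(0x0008L, 0x0016L, "UI", DICOM_CT_SOP_CLASS),
      dcm_el_str(0x0008L, 0x0018L, "UI", paste0(series_uid, ".", k)),
      dcm_el_str(0x0008L, 0x0060L, "CS", "CT"),
      dcm_el_str(0x0020L, 0x000dL, "UI", paste0(series_uid, ".0")),
      dcm_el_str(0x0020L, 0x000eL, "UI", series_uid),
      dcm_el_str(0x0020L, 0x0013L, "IS", as.character(k)),
      dcm_el_str(0x0020L, 0x0032L, "DS",
                 paste(format(c(vol$origin[2], vol$origin[1], z), trim = TRUE),
                       collapse = "\\")),
      dcm_el_str(0x0020L, 0x0037L, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_el_us(0x0028L, 0x0002L, 1L),
      dcm_el_str(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      dcm_el_us(0x0028L, 0x0010L, nrow(sl)),
      dcm_el_us(0x0028L, 0x0011L, ncol(sl)),
      dcm_el_str(0x0028L, 0x0030L, "DS",
                 paste(format(vol$spacing[1:2], trim = TRUE), collapse = "\\")),
      dcm_el_str(0x0018L, 0x0050L, "DS", format(vol$spacing[3], trim = TRUE)),
      dcm_el_us(0x0028L, 0x0100L, 16L),
      dcm_el_us(0x0028L, 0x0101L, 16L),
      dcm_el_us(0x0028L, 0x0102L, 15L),
      dcm_el_us(0x0028L, 0x0103L, 1L),
      dcm_el_str(0x0028L, 0x1052L, "DS", format(intercept, trim = TRUE)),
      dcm_el_str(0x0028L, 0x1053L, "DS", "1"),
      dcm_el_explicit(0x7fe0L, 0x0010L, "OW",
                      writeBin(as.integer(t(sl)), raw(), size = 2L,
                               endian = "little"))
    )
    meta <- c(
      dcm_el_explicit(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
      dcm_el_str(0x0002L, 0x0002L, "UI", DICOM_CT_SOP_CLASS),
      dcm_el_str(0x0002L, 0x0003L, "UI", paste0(series_uid, ".", k)),
      dcm_el_str(0x0002L, 0x0010L, "UI", DICOM_TS_EXPLICIT_LE)
    )
    grplen <- dcm_el_explicit(0x0002L, 0x0000L, "UL",
                              writeBin(length(meta), raw(), size = 4L,
                                       endian = "little"))
    path <- file.path(dir, sprintf("slice_%03d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), grplen, meta, ds), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}
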