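#' Read a CT series into Hounsfield units
#'
#' Reads either a directory containing a single-series DICOM stack (one slice
#' per file) or a single NIfTI-1 volume, returning a [ct_volume()] in
#' Hounsfield units with physical spacing populated from the headers.
#'
#' DICOM stored values are converted per slice with the linear rescale
#' `HU = stored * slope + intercept`. Slices are sorted by their physical
#' position along the scan axis, independent of on-disk file order. If the
#' rescale tags are absent the CT convention (slope 1, intercept -1024) is
#' applied and the volume is flagged `"default_rescale"` with a warning.
#' A directory mixing series UIDs or lacking pixel-spacing information is an
#' error.
#'
#' @param path directory with `.dcm`/`.ima` files (or any files that parse as
#'   DICOM), or the path of a `.nii`/`.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(path) {
  if (dir.exists(path)) return(read_dicom_dir(path))
  if (!file.exists(path)) stop("no such path: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_ct_nifti(path))
  stop("unsupported input (expected a DICOM directory or a NIfTI file): ", path)
}

read_dicom_dir <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("empty DICOM directory: ", path)
  slices <- lapply(files, dcm_read_slice)

  uids <- unique(vapply(slices, function(s)
    if (is.null(s$series_uid)) "" else s$series_uid, ""))
  if (length(uids) > 1L)
    stop("mixed DICOM series in ", path, " (", length(uids), " series UIDs)")
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), integer(2))))
  if (nrow(dims) > 1L) stop("inconsistent slice dimensions in ", path)

  sp <- slices[[1L]]$spacing
  if (is.null(sp) || length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid PixelSpacing in ", path)

  z <- vapply(slices, function(s)
    if (is.null(s$position)) NA_real_ else s$position[3], 0)
  if (anyNA(z)) {
    inst <- vapply(slices, function(s)
      if (is.null(s$instance)) NA_real_ else s$instance[1], 0)
    if (anyNA(inst)) stop("slices carry neither position nor instance number")
    z <- inst
  }
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]

  flags <- character()
  grids <- lapply(slices, function(s) {
    slope <- s$slope; inter <- s$intercept
    if (is.null(slope) || is.null(inter)) {
      slope <- 1; inter <- -1024
      flags <<- unique(c(flags, "default_rescale"))
    }
    s$stored * slope + inter
  })
  if ("default_rescale" %in% flags)
    warning("rescale tags absent; applied CT default (slope 1, intercept -1024)")

  dz <- if (length(z) > 1L) mean(diff(z)) else slices[[1L]]$thickness
  if (is.null(dz) || !is.finite(dz) || dz <= 0) dz <- 1
  pos1 <- slices[[1L]]$position
  origin <- if (!is.null(pos1)) c(pos1[2], pos1[1], pos1[3]) else c(0, 0, 0)

  vox <- array(unlist(grids), dim = c(dims[1, 1], dims[1, 2], length(grids)))
  ct_volume(vox, spacing = c(sp[1], sp[2], dz), origin = origin,
            source_id = path, flags = flags)
}

read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  pd <- RNifti::pixdim(img)
  hdr <- RNifti::niftiHeader(img)
  ct_volume(arr, spacing = pd[1:3],
            origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z),
            source_id = path)
}

#' Write a CT volume or mask as NIfTI-1
#'
#' Volumes are stored as float64 (bit-exact round trip); masks as uint8
#' labels (1 = foreground).
#'
#' @param x a [ct_volume()] or [seg_mask()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels
    sp <- x$spacing
  } else if (inherits(x, "seg_mask")) {
    arr <- array(as.integer(x$grid), dim = dim(x$grid))
    sp <- attr(x, "spacing")
    if (is.null(sp)) sp <- c(1, 1, 1)
  } else stop("x must be a ct_volume or seg_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an aorta mask aligned to a CT volume
#'
#' Accepts either a volume-aligned NIfTI label image (nonzero = aorta) or a
#' CSV of per-slice closed polygons. Polygons are rasterized with the
#' pixel-center-inside rule (even-odd crossing test); vertices are physical
#' coordinates in mm (`x` along columns, `y` along rows, relative to the
#' volume origin).
#'
#' @param path NIfTI label image, or polygon CSV with columns
#'   `slice` (1-based), `x_mm`, `y_mm`, vertices in drawing order per slice.
#' @param reference the [ct_volume()] the mask belongs to.
#' @param tol relative tolerance for the spacing check against the reference
#'   (label images only).
#' @return A [seg_mask()] with provenance `"external_file"`.
#' @export
read_mask <- function(path, reference, tol = 1e-3) {
  stopifnot(inherits(reference, "ct_volume"))
  if (grepl("\\.csv$", path)) return(read_polygon_mask(path, reference))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (!identical(dim(arr), dim(reference$voxels)))
    stop("mask shape ", paste(dim(arr), collapse = "x"),
         " does not match volume shape ",
         paste(dim(reference$voxels), collapse = "x"))
  sp <- RNifti::pixdim(img)[1:3]
  rel <- abs(sp - reference$spacing) / reference$spacing
  if (any(rel > tol))
    stop("mask spacing deviates from volume spacing beyond tolerance")
  seg_mask(arr != 0, provenance = "external_file", reference = reference)
}

# Even-odd crossing test: is the point (px, py) inside the closed polygon?
# Half-open edge rule gives deterministic results for points on edges.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

read_polygon_mask <- function(path, reference) {
  df <- read.csv(path)
  need <- c("slice", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("polygon CSV must have columns: ", paste(need, collapse = ", "))
  d <- dim(reference$voxels)
  grid <- array(FALSE, d)
  sr <- reference$spacing[1]; sc <- reference$spacing[2]
  cy <- (seq_len(d[1]) - 1) * sr # row centers (y), relative to origin
  cx <- (seq_len(d[2]) - 1) * sc # column centers (x)
  pts <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  for (k in unique(df$slice)) {
    if (k < 1 || k > d[3]) stop("polygon slice index out of range: ", k)
    poly <- df[df$slice == k, ]
    inside <- point_in_polygon(cx[pts$col], cy[pts$row], poly$x_mm, poly$y_mm)
    sl <- grid[, , k]
    sl[cbind(pts$row, pts$col)] <- inside
    grid[, , k] <- sl
  }
  seg_mask(grid, provenance = "external_file", reference = reference)
}

#' Write the per-patient analysis report
#'
#' One row per patient with a fixed, stable column order. Numeric fields are
#' written at full double precision so re-reading the CSV reproduces them.
#'
#' @param results list of [fai_result()] objects (possibly named by id), or a
#'   data frame already in report layout.
#' @param path output CSV path.
#' @param records optional data frame of patient records (matched by `id`)
#'   whose columns are appended after the imaging columns.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(results, path, records = NULL) {
  cols <- c("id", "aa_fai_hu", "ct_pvat_area_mm2_per_slice", "n_fat_pixels",
            "n_ring_pixels", "n_slices", "flags")
  if (is.data.frame(results)) {
    df <- results
  } else {
    rows <- lapply(seq_along(results), function(i) {
      r <- results[[i]]
      id <- if (!is.null(names(results)) && nzchar(names(results)[i]))
        names(results)[i] else as.character(i)
      data.frame(id = id,
                 aa_fai_hu = if (is.null(r$aa_fai)) NA_real_ else r$aa_fai,
                 ct_pvat_area_mm2_per_slice = r$ct_pvat_area,
                 n_fat_pixels = r$n_fat_pixels,
                 n_ring_pixels = r$n_ring_pixels,
                 n_slices = r$n_slices,
                 flags = paste(r$flags, collapse = ";"))
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  df <- df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
  if (!is.null(records) && nrow(df))
    df <- merge(df, records, by = "id", all.x = TRUE, sort = FALSE)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE)
  invisible(df)
}
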