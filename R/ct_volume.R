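#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of CT attenuation in Hounsfield units (HU)
#' together with its physical geometry. Voxel indices are 1-based in R; the
#' physical position of a voxel center is `origin + (index - 1) * spacing`.
#'
#' @param voxels numeric 3-D array `[rows, cols, slices]` of attenuation (HU).
#' @param spacing numeric length-3: row, column and slice spacing in mm.
#' @param origin numeric length-3 physical position of the first voxel center
#'   (mm). Default `c(0, 0, 0)`.
#' @param source_id opaque identifier for provenance (file path, phantom tag).
#' @param flags character vector of quality flags accumulated during reading
#'   (e.g. `"default_rescale"`, `"hu_out_of_range"`).
#' @param validate check invariants (positive spacing, finite voxels, HU in
#'   the physical CT range \[-1100, 3200\]). An out-of-range HU adds the
#'   `"hu_out_of_range"` flag with a warning rather than failing.
#'
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing`, `origin`, `slice_count`, `source_id`, `flags`.
#' @export
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 2)), spacing = c(0.7, 0.7, 5))
#' v$slice_count
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      source_id = "memory", flags = character(),
                      validate = TRUE) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array [rows, cols, slices]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L) stop("spacing must have 3 components (mm)")
  vol <- structure(list(
    voxels = voxels, spacing = spacing, origin = as.numeric(origin),
    slice_count = dim(voxels)[3L], source_id = source_id,
    flags = unique(flags)), class = "ct_volume")
  if (validate) vol <- validate_ct_volume(vol)
  vol
}

validate_ct_volume <- function(vol) {
  if (any(!is.finite(vol$spacing)) || any(vol$spacing <= 0))
    stop("all spacing components must be positive and finite")
  if (vol$slice_count != dim(vol$voxels)[3L])
    stop("slice_count must equal the third grid dimension")
  if (any(!is.finite(vol$voxels)))
    stop("voxels must be finite")
  rng <- range(vol$voxels)
  if (rng[1] < -1100 || rng[2] > 3200) {
    warning("HU outside the physical CT range [-1100, 3200]; flagged")
    vol$flags <- unique(c(vol$flags, "hu_out_of_range"))
  }
  vol
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], source '%s'%s\n",
              min(x$voxels), max(x$voxels), x$source_id,
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ", ")) else ""))
  invisible(x)
}

#' Segmentation mask container
#'
#' A boolean grid aligned voxel-for-voxel with a [ct_volume()], marking the
#' ascending aorta (or a derived region such as the perivascular ring).
#' Slices without any foreground voxel are flagged undetected.
#'
#' @param grid logical 3-D array, same shape as the paired volume.
#' @param target what the mask delineates; currently `"ascending_aorta"`.
#' @param provenance one of `"classical_detector"`, `"external_file"`,
#'   `"ground_truth"`, `"derived"`.
#' @param reference optional `ct_volume`; if given, the grid shape is checked
#'   against it.
#'
#' @return An object of class `seg_mask`: list with `grid`, `target`,
#'   `provenance`, `undetected` (logical per slice).
#' @export
seg_mask <- function(grid, target = "ascending_aorta",
                     provenance = c("classical_detector", "external_file",
                                    "ground_truth", "derived"),
                     reference = NULL) {
  provenance <- match.arg(provenance)
  if (length(dim(grid)) != 3L) stop("mask grid must be a 3-D array")
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) stop("mask grid must not contain NA")
  if (!is.null(reference) && !identical(dim(grid), dim(reference$voxels)))
    stop("mask grid shape must equal the paired CT volume shape")
  undetected <- apply(grid, 3L, function(s) !any(s))
  structure(list(grid = grid, target = target, provenance = provenance,
                 undetected = undetected), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<seg_mask> %s (%s): %d x %d x %d, %d foreground voxels, %d/%d slices detected\n",
              x$target, x$provenance, d[1], d[2], d[3], sum(x$grid),
              sum(!x$undetected), d[3]))
  invisible(x)
}

# Physical in-plane pixel area in mm^2.
pixel_area <- function(vol) vol$spacing[1] * vol$spacing[2]
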