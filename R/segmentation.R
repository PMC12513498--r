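#' Configuration of the classical ascending-aorta detector
#'
#' @param lumen_hu_threshold minimum attenuation of contrast-filled lumen
#'   pixels, HU.
#' @param radius_range admissible equivalent radius (mm) of a candidate
#'   cross-section, `c(min, max)`.
#' @param min_circularity minimum isoperimetric quotient `4*pi*A/P^2` of a
#'   candidate, in `(0, 1]`. The perimeter is the Cauchy-Crofton-corrected
#'   exposed-edge length (`pi/4` times the Manhattan boundary length), which
#'   is approximately unbiased for smooth convex shapes.
#' @param extent_mm length of aorta analyzed distal to the anchor slice, mm.
#' @return A `detector_config` list.
#' @export
detector_config <- function(lumen_hu_threshold = 150,
                            radius_range = c(10, 25),
                            min_circularity = 0.8,
                            extent_mm = 50) {
  stopifnot(radius_range[1] < radius_range[2], extent_mm > 0,
            min_circularity > 0, min_circularity <= 1)
  structure(list(lumen_hu_threshold = lumen_hu_threshold,
                 radius_range = radius_range,
                 min_circularity = min_circularity,
                 extent_mm = extent_mm), class = "detector_config")
}

# Per-component geometry of a labelled slice: area (mm^2), equivalent radius
# (mm), corrected-perimeter circularity, centroid (mm).
component_stats <- function(lab, sr, sc) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (!length(ids)) return(NULL)
  nr <- nrow(lab); nc <- ncol(lab)
  out <- lapply(ids, function(id) {
    m <- lab == id
    npix <- sum(m)
    area <- npix * sr * sc
    # exposed 4-neighbour edges; a missing row-neighbour exposes an edge of
    # length sc (and vice versa)
    up    <- m & !rbind(FALSE, m[-nr, , drop = FALSE])
    down  <- m & !rbind(m[-1, , drop = FALSE], FALSE)
    left  <- m & !cbind(FALSE, m[, -nc, drop = FALSE])
    right <- m & !cbind(m[, -1, drop = FALSE], FALSE)
    p_manhattan <- (sum(up) + sum(down)) * sc + (sum(left) + sum(right)) * sr
    perim <- p_manhattan * pi / 4
    idx <- which(m, arr.ind = TRUE)
    data.frame(id = id, n_pixels = npix, area_mm2 = area,
               r_eq_mm = sqrt(area / pi),
               circularity = 4 * pi * area / perim^2,
               centroid_row_mm = mean((idx[, 1] - 1) * sr),
               centroid_col_mm = mean((idx[, 2] - 1) * sc))
  })
  do.call(rbind, out)
}

#' Detect the ascending aorta with a classical threshold detector
#'
#' Per slice: threshold at the lumen attenuation, label 4-connected
#' components, keep components whose equivalent radius lies in the configured
#' range and whose circularity meets the minimum, and track the vessel across
#' slices by nearest centroid (the first analyzed slice takes the most
#' circular candidate). Ties break toward higher circularity, then the
#' smaller centroid row. The returned mask is the filled cross-section of the
#' selected component on each detected slice.
#'
#' This detector stands in for a trained segmentation model on data with
#' clean contrast semantics (phantoms, well-opacified scans); externally
#' produced masks can be supplied through [read_mask()] instead.
#'
#' @param volume a [ct_volume()].
#' @param config a [detector_config()].
#' @return List with `mask` ([seg_mask()], provenance
#'   `"classical_detector"`) and `report`: per-slice `detected` flag and
#'   `circularity`, overall `success` flag, and `fraction_detected`.
#' @export
detect_aorta_classical <- function(volume, config = detector_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  sr <- volume$spacing[1]; sc <- volume$spacing[2]
  grid <- array(FALSE, d)
  detected <- logical(d[3])
  circ <- rep(NA_real_, d[3])
  prev_center <- NULL
  for (k in seq_len(d[3])) {
    bw <- volume$voxels[, , k] >= config$lumen_hu_threshold
    if (!any(bw)) next
    lab <- EBImage::imageData(EBImage::bwlabel(bw))
    st <- component_stats(lab, sr, sc)
    st <- st[st$r_eq_mm >= config$radius_range[1] &
             st$r_eq_mm <= config$radius_range[2] &
             st$circularity >= config$min_circularity, , drop = FALSE]
    if (is.null(st) || !nrow(st)) next
    if (is.null(prev_center)) {
      ord <- order(-st$circularity, st$centroid_row_mm)
    } else {
      dd <- sqrt((st$centroid_row_mm - prev_center[1])^2 +
                 (st$centroid_col_mm - prev_center[2])^2)
      ord <- order(dd, -st$circularity, st$centroid_row_mm)
    }
    sel <- st[ord[1], ]
    comp <- EBImage::imageData(EBImage::fillHull(lab == sel$id))
    grid[, , k] <- comp > 0
    detected[k] <- TRUE
    circ[k] <- sel$circularity
    prev_center <- c(sel$centroid_row_mm, sel$centroid_col_mm)
  }
  mask <- seg_mask(grid, provenance = "classical_detector")
  report <- list(detected = detected, circularity = circ,
                 success = any(detected),
                 fraction_detected = mean(detected))
  list(mask = mask, report = report)
}

#' Select the analyzed slice extent
#'
#' Returns the contiguous run of `ceiling(extent_mm / slice spacing)` slices
#' starting at the anchor (by default the first detected slice in ascending
#' slice order), truncated at the end of the volume with a flag.
#'
#' @param mask a [seg_mask()] from detection or an external file.
#' @param volume the paired [ct_volume()].
#' @param config a [detector_config()] supplying `extent_mm`.
#' @param anchor optional anchor slice index overriding the default.
#' @return List with `slices` (integer vector) and `truncated` (logical).
#' @export
select_extent <- function(mask, volume, config = detector_config(),
                          anchor = NULL) {
  stopifnot(inherits(mask, "seg_mask"), inherits(volume, "ct_volume"))
  det <- which(!mask$undetected)
  if (!length(det)) stop("no detected slices; cannot select an extent")
  if (is.null(anchor)) anchor <- det[1]
  n_slices <- ceiling(config$extent_mm / volume$spacing[3])
  last <- anchor + n_slices - 1L
  truncated <- last > volume$slice_count
  list(slices = seq.int(anchor, min(last, volume$slice_count)),
       truncated = truncated)
}
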