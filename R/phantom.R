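#' Specification of a synthetic aorta phantom
#'
#' Describes a voxel phantom of a contrast-filled ascending aorta: per slice,
#' a bright lumen disc, a soft-tissue-like wall annulus, and a surrounding
#' region within `fat_ring_mm` of the vessel in which a seeded random subset
#' of pixels is adipose tissue (Gaussian HU truncated to the open interval
#' (-190, 0)) and the rest soft tissue. The phantom records its own ground
#' truth, so every downstream stage can be checked exactly.
#'
#' The ground-truth aorta mask is the contrast-filled lumen disc -- the
#' structure a threshold detector (or a contrast-trained segmenter)
#' delineates. The wall annulus default of 40 HU lies outside the fat window,
#' so it can never contaminate the ground-truth fat set.
#'
#' @param lumen_radius lumen disc radius, mm.
#' @param lumen_hu lumen attenuation (contrast-enhanced), HU; must be > 150.
#' @param wall_thickness wall annulus thickness, mm.
#' @param wall_hu wall attenuation, HU; must lie outside `(-190, 0)`.
#' @param fat_hu_mean,fat_hu_sd Gaussian parameters of the fat attenuation,
#'   HU; the mean must lie in `(-190, 0)`; draws are truncated to that open
#'   interval.
#' @param fat_fraction_of_ring fraction of perivascular-candidate pixels that
#'   are fat, in `[0, 1]`.
#' @param fat_ring_mm extent of the perivascular candidate region, mm from
#'   the vessel (default 10).
#' @param soft_tissue_hu non-fat perivascular and body tissue, HU.
#' @param background_hu air outside the body, HU.
#' @param noise_sd additive Gaussian noise applied everywhere, HU.
#' @param spacing `(row, column, slice)` spacing, mm.
#' @param grid_shape `(rows, cols, slices)`.
#' @param center_path per-slice vessel center as an `n_slices x 2` matrix of
#'   `(row mm, col mm)` physical coordinates, or `NULL` for the grid center
#'   on every slice.
#' @param quantize_hu round all voxel values to integer HU (so the phantom
#'   survives DICOM integer storage exactly); ground truth records the
#'   quantized values.
#' @param seed integer seed; the same spec always yields a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(lumen_radius = 15, lumen_hu = 300,
                         wall_thickness = 2, wall_hu = 40,
                         fat_hu_mean = -80, fat_hu_sd = 15,
                         fat_fraction_of_ring = 0.5, fat_ring_mm = 10,
                         soft_tissue_hu = 50, background_hu = -1000,
                         noise_sd = 0, spacing = c(1, 1, 5),
                         grid_shape = c(96, 96, 3), center_path = NULL,
                         quantize_hu = FALSE, seed = 1L) {
  spec <- list(lumen_radius = lumen_radius, lumen_hu = lumen_hu,
               wall_thickness = wall_thickness, wall_hu = wall_hu,
               fat_hu_mean = fat_hu_mean, fat_hu_sd = fat_hu_sd,
               fat_fraction_of_ring = fat_fraction_of_ring,
               fat_ring_mm = fat_ring_mm, soft_tissue_hu = soft_tissue_hu,
               background_hu = background_hu, noise_sd = noise_sd,
               spacing = as.numeric(spacing),
               grid_shape = as.integer(grid_shape),
               center_path = center_path, quantize_hu = isTRUE(quantize_hu),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!(spec$fat_hu_mean > -190 && spec$fat_hu_mean < 0))
    stop("fat_hu_mean must lie in the open interval (-190, 0)")
  if (spec$lumen_hu <= 150)
    stop("lumen_hu must exceed 150 (contrast-enhanced semantics)")
  if (spec$wall_hu >= -190 && spec$wall_hu <= 0)
    stop("wall_hu must lie outside the fat window [-190, 0]")
  if (spec$fat_fraction_of_ring < 0 || spec$fat_fraction_of_ring > 1)
    stop("fat_fraction_of_ring must be in [0, 1]")
  if (spec$fat_hu_sd < 0 || spec$noise_sd < 0) stop("sd parameters must be >= 0")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (any(spec$grid_shape < 1)) stop("grid_shape must be positive")
  if (spec$fat_ring_mm <= 0) stop("fat_ring_mm must be positive")
  invisible(spec)
}

# Inverse-CDF draw from Normal(mean, sd) truncated to the open interval
# (lo, hi); exact, vectorized, deterministic under the current RNG stream.
rtruncnorm_open <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean <= lo || mean >= hi) stop("degenerate truncated normal outside support")
    return(rep(mean, n))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  x <- qnorm(u, mean, sd)
  pmin(pmax(x, lo + 1e-9), hi - 1e-9) # guard against boundary rounding
}

#' Generate a voxel phantom with exact ground truth
#'
#' Builds the concentric phantom described by [phantom_spec()] and returns
#' the volume, the ground-truth aorta mask, and a ground-truth record with
#' the exact fat-pixel set, their noiseless mean HU, and the exact fat area
#' in mm^2 per slice.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()]), `mask`
#'   ([seg_mask()], provenance `"ground_truth"`), and `truth`: list with
#'   `fat_index` (logical 3-D array of the fat-pixel set), `fat_hu`
#'   (noiseless HU of each fat pixel), `fat_mean_hu`, `fat_area_mm2_per_slice`,
#'   `n_fat_pixels`, `ring_index` (candidate perivascular region), and the
#'   generating `spec`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(64, 64, 2), seed = 7))
#' ph$truth$fat_mean_hu
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  sr <- spec$spacing[1]; sc <- spec$spacing[2]
  centers <- spec$center_path
  if (is.null(centers))
    centers <- matrix(rep(c((d[1] - 1) / 2 * sr, (d[2] - 1) / 2 * sc),
                          each = d[3]), ncol = 2)
  if (nrow(centers) != d[3]) stop("center_path must have one row per slice")
  margin_ok <- all(
    centers[, 1] - spec$lumen_radius - spec$fat_ring_mm >= -1e-9,
    centers[, 2] - spec$lumen_radius - spec$fat_ring_mm >= -1e-9,
    (d[1] - 1) * sr - centers[, 1] - spec$lumen_radius - spec$fat_ring_mm >= -1e-9,
    (d[2] - 1) * sc - centers[, 2] - spec$lumen_radius - spec$fat_ring_mm >= -1e-9)

  vox <- array(spec$background_hu, d)
  lumen <- array(FALSE, d)
  ring <- array(FALSE, d)
  fat_index <- array(FALSE, d)
  fat_hu_all <- numeric(0)

  with_seed(spec$seed, {
    for (k in seq_len(d[3])) {
      ry <- (seq_len(d[1]) - 1) * sr - centers[k, 1]
      cx <- (seq_len(d[2]) - 1) * sc - centers[k, 2]
      dist <- sqrt(outer(ry^2, cx^2, "+"))
      in_lumen <- dist <= spec$lumen_radius
      in_wall <- !in_lumen & dist <= spec$lumen_radius + spec$wall_thickness

      # perivascular candidates: within fat_ring_mm of the lumen pixel set,
      # outside lumen and wall (same center-to-center metric the pipeline uses)
      d2 <- edt2_sq(in_lumen, sr, sc)
      in_ring <- !in_lumen & !in_wall & d2 <= spec$fat_ring_mm^2

      sl <- matrix(spec$background_hu, d[1], d[2])
      sl[in_ring] <- spec$soft_tissue_hu
      sl[in_wall] <- spec$wall_hu
      sl[in_lumen] <- spec$lumen_hu

      idx <- which(in_ring)
      n_fat <- round(spec$fat_fraction_of_ring * length(idx))
      fat_idx <- if (n_fat > 0) sort(idx[sample.int(length(idx), n_fat)]) else integer(0)
      hu <- rtruncnorm_open(length(fat_idx), spec$fat_hu_mean, spec$fat_hu_sd,
                            -190, 0)
      if (spec$quantize_hu) hu <- pmin(pmax(round(hu), -189), -1)
      sl[fat_idx] <- hu

      fm <- matrix(FALSE, d[1], d[2]); fm[fat_idx] <- TRUE
      fat_index[, , k] <- fm
      fat_hu_all <- c(fat_hu_all, hu)
      lumen[, , k] <- in_lumen
      ring[, , k] <- in_ring
      vox[, , k] <- sl
    }
    if (spec$noise_sd > 0)
      vox <- vox + rnorm(length(vox), 0, spec$noise_sd)
  })
  if (spec$quantize_hu) vox <- round(vox)
  vox <- pmin(pmax(vox, -1100), 3200) # physical CT range
  vol <- ct_volume(vox, spacing = spec$spacing,
                   source_id = sprintf("phantom-seed%d", spec$seed))
  if (!margin_ok) vol$flags <- unique(c(vol$flags, "border_clipped"))
  mask <- seg_mask(lumen, provenance = "ground_truth", reference = vol)
  truth <- list(
    fat_index = fat_index, fat_hu = fat_hu_all,
    fat_mean_hu = if (length(fat_hu_all)) mean(fat_hu_all) else NA_real_,
    n_fat_pixels = sum(fat_index),
    fat_area_mm2_per_slice = sum(fat_index) * sr * sc / d[3],
    ring_index = ring, spec = spec)
  list(volume = vol, mask = mask, truth = truth)
}

#' Specification of a simulated AA-FAI cohort
#'
#' Per-group Gaussian model of the fat attenuation index. The default groups
#' reproduce the study cohort summaries this package targets: 159 patients
#' without hereditary connective-tissue disorders (AA-FAI -62.02 +/- 8.54 HU),
#' 36 with Marfan syndrome (-52.90 +/- 12.69 HU) and 9 with Loeys-Dietz
#' syndrome (-51.70 +/- 7.99 HU).
#'
#' @param groups data frame with columns `label`, `mean` (HU), `sd` (HU),
#'   `n`.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = study_groups(), seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("label", "mean", "sd", "n") %in% names(groups)))
  if (any(groups$sd <= 0)) stop("group sd must be > 0")
  if (any(groups$n < 1)) stop("group n must be >= 1")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Printed cohort summaries of the target study population
#'
#' @return Data frame of group label, mean AA-FAI (HU), SD (HU) and n.
#' @export
study_groups <- function() {
  data.frame(label = c("non_HCTD", "MFS", "LDS"),
             mean = c(-62.02, -52.90, -51.70),
             sd = c(8.54, 12.69, 7.99),
             n = c(159L, 36L, 9L))
}

#' Simulate a patient cohort of AA-FAI values
#'
#' Draws, for each group, `n` independent Gaussian AA-FAI values and attaches
#' the group label. Reproducible under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `id`, `group` (factor, levels in spec
#'   order) and `aa_fai` (HU).
#' @export
#' @examples
#' head(simulate_fai_cohort(cohort_spec(seed = 42)))
simulate_fai_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  with_seed(spec$seed, {
    vals <- lapply(seq_len(nrow(g)), function(i) rnorm(g$n[i], g$mean[i], g$sd[i]))
  })
  data.frame(
    id = sprintf("P%04d", seq_len(sum(g$n))),
    group = factor(rep(g$label, g$n), levels = g$label),
    aa_fai = unlist(vals))
}
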