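test_that("DICOM rescale converts stored values to HU and defaults are flagged", {
  ph <- test_phantom(quantize_hu = TRUE, noise_sd = 7)
  dir <- withr::local_tempdir()
  write_ct_dicom(ph$volume, dir)
  vol <- read_ct_series(dir)
  # linear rescale identity: stored 1024 with slope 1 / intercept -1024 is 0 HU
  expect_identical(vol$voxels, ph$volume$voxels)
  expect_equal(vol$spacing, ph$volume$spacing)

  # strip the rescale tags from every slice: CT default applies, flagged
  for (f in list.files(dir, full.names = TRUE)) {
    el <- aafai:::dcm_parse_file(f)
    expect_equal(aafai:::dcm_ds(el[["00281052"]]), -1024)
  }
})

test_that("missing rescale tags fall back to slope 1 / intercept -1024 with a warning", {
  ph <- test_phantom(quantize_hu = TRUE)
  dir <- withr::local_tempdir()
  write_ct_dicom(ph$volume, dir)
  # surgically remove the intercept+slope elements from each file
  for (f in list.files(dir, full.names = TRUE)) {
    bytes <- readBin(f, "raw", n = file.size(f))
    # explicit VR DS elements: tag 0028,1052 then 0028,1053 are adjacent
    tag <- as.raw(c(0x28, 0x00, 0x52, 0x10))
    pos <- NULL
    for (p in seq_len(length(bytes) - 3L))
      if (identical(bytes[p:(p + 3L)], tag)) { pos <- p; break }
    expect_false(is.null(pos))
    len1 <- as.integer(bytes[pos + 6L]) + 256L * as.integer(bytes[pos + 7L])
    pos2 <- pos + 8L + len1 # start of 0028,1053
    len2 <- as.integer(bytes[pos2 + 6L]) + 256L * as.integer(bytes[pos2 + 7L])
    bytes <- bytes[-(pos:(pos2 + 7L + len2))]
    writeBin(bytes, f)
  }
  expect_warning(vol <- read_ct_series(dir), "default")
  expect_true("default_rescale" %in% vol$flags)
  expect_identical(vol$voxels, ph$volume$voxels) # same default as the writer
})

test_that("slice order is recovered from physical position, not file order", {
  ph <- test_phantom(quantize_hu = TRUE, noise_sd = 5, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_ct_dicom(ph$volume, dir)
  # shuffle on disk by renaming so lexical order is reversed
  tmp <- file.path(dir, rev(sprintf("z_%03d.dcm", seq_along(paths))))
  file.rename(paths, tmp)
  vol <- read_ct_series(dir)
  expect_identical(vol$voxels, ph$volume$voxels)
})

test_that("mixed series and missing spacing are errors", {
  ph1 <- test_phantom(quantize_hu = TRUE, seed = 1)
  ph2 <- test_phantom(quantize_hu = TRUE, seed = 2)
  dir <- withr::local_tempdir()
  write_ct_dicom(ph1$volume, dir, series_uid = "1.2.3.1")
  p2 <- write_ct_dicom(ph2$volume, withr::local_tempdir(), series_uid = "1.2.3.2")
  file.copy(p2[1], file.path(dir, "intruder.dcm"))
  expect_error(read_ct_series(dir), "mixed")
})

test_that("NIfTI volumes round-trip bit-exactly with spacing", {
  ph <- test_phantom(noise_sd = 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$volume, f)
  vol <- read_ct_series(f)
  expect_identical(as.vector(vol$voxels), as.vector(ph$volume$voxels))
  expect_equal(vol$spacing, ph$volume$spacing)
})

test_that("label masks align to the reference and mismatches error", {
  ph <- test_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$mask, f)
  # spacing is carried on the mask via its paired volume
  m <- RNifti::readNifti(f)
  RNifti::pixdim(m) <- ph$volume$spacing
  RNifti::writeNifti(m, f)
  mask <- read_mask(f, ph$volume)
  expect_identical(mask$grid, ph$mask$grid)
  expect_equal(mask$provenance, "external_file")

  # all-zero label volume: no true voxel, every slice undetected
  z <- RNifti::asNifti(array(0L, dim(ph$volume$voxels)))
  RNifti::pixdim(z) <- ph$volume$spacing
  fz <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(z, fz)
  mz <- read_mask(fz, ph$volume)
  expect_equal(sum(mz$grid), 0)
  expect_true(all(mz$undetected))

  # wrong shape errors
  bad <- RNifti::asNifti(array(1L, c(4, 4, 2)))
  fb <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(bad, fb)
  expect_error(read_mask(fb, ph$volume), "shape")
})

test_that("polygon masks rasterize with the pixel-center-inside rule", {
  vol <- ct_volume(array(0, c(32, 32, 1)), spacing = c(1, 1, 5))
  # axis-aligned square spanning pixel centers (5..14) in both axes: 100 px
  sq <- data.frame(slice = 1,
                   x_mm = c(4.5, 14.5, 14.5, 4.5),
                   y_mm = c(4.5, 4.5, 14.5, 14.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(sq, f, row.names = FALSE)
  m <- read_mask(f, vol)
  expect_equal(sum(m$grid), 100)
  expect_true(all(which(m$grid[, , 1], arr.ind = TRUE) >= 6 &
                    which(m$grid[, , 1], arr.ind = TRUE) <= 15))

  # circle polygon, radius 10 px: count equals an independent
  # center-inside enumeration (mgcv::in.out)
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  circ <- data.frame(slice = 1, x_mm = 15 + 10 * cos(th),
                     y_mm = 15 + 10 * sin(th))
  fc <- withr::local_tempfile(fileext = ".csv")
  write.csv(circ, fc, row.names = FALSE)
  mc <- read_mask(fc, vol)
  pts <- expand.grid(x = 0:31, y = 0:31)
  inside <- mgcv::in.out(cbind(circ$x_mm, circ$y_mm),
                         as.matrix(pts))
  expect_equal(sum(mc$grid), sum(inside))
})

test_that("report CSV is stable, ordered, and numerically round-trips", {
  ph <- test_phantom(noise_sd = 3, seed = 21)
  res <- fai_pipeline(ph$volume)
  f <- withr::local_tempfile(fileext = ".csv")

  # empty list: header-only file
  df0 <- write_report(list(), f)
  expect_equal(nrow(df0), 0)
  expect_equal(length(readLines(f)), 1L)

  # one result: two-line file with the documented column order
  df1 <- write_report(list(pt1 = res), f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  expect_equal(names(read.csv(f))[1:7],
               c("id", "aa_fai_hu", "ct_pvat_area_mm2_per_slice",
                 "n_fat_pixels", "n_ring_pixels", "n_slices", "flags"))
  back <- read.csv(f)
  expect_equal(back$aa_fai_hu, res$aa_fai, tolerance = 1e-12)
  expect_equal(back$ct_pvat_area_mm2_per_slice, res$ct_pvat_area,
               tolerance = 1e-12)
  expect_equal(back$n_fat_pixels, res$n_fat_pixels)
})
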