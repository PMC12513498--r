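make_disc_volume <- function(n = 48, radius_px = 10, spacing = c(1, 1, 5),
                             center = NULL, hu = -100) {
  if (is.null(center)) center <- c((n - 1) / 2, (n - 1) / 2)
  ry <- (seq_len(n) - 1) - center[1]
  cx <- (seq_len(n) - 1) - center[2]
  disc <- sqrt(outer(ry^2, cx^2, "+")) <= radius_px
  vox <- array(hu, c(n, n, 1))
  vol <- ct_volume(vox, spacing = spacing)
  mask <- seg_mask(array(disc, c(n, n, 1)))
  list(vol = vol, mask = mask, disc = disc)
}

test_that("the ring matches brute force for a disc and scales with spacing", {
  d <- make_disc_volume(n = 64, radius_px = 10)
  ring <- perivascular_ring(d$mask, d$vol, ring_params(ring_distance = 10))
  # ~ annulus pi(20^2 - 10^2) ~= 942 px at 1 mm spacing
  n_ring <- sum(ring$grid)
  oracle <- bf_ring(d$disc, 1, 1, 10)
  expect_identical(ring$grid[, , 1], oracle)
  expect_lt(abs(n_ring - pi * (20^2 - 10^2)), 40)
  expect_equal(sum(ring$grid & d$mask$grid), 0) # disjoint from the vessel

  # 0.5 mm spacing: ring twice as thick in pixels, still disjoint
  d2 <- make_disc_volume(n = 128, radius_px = 20, spacing = c(0.5, 0.5, 5))
  ring2 <- perivascular_ring(d2$mask, d2$vol, ring_params(ring_distance = 10))
  expect_identical(ring2$grid[, , 1], bf_ring(d2$disc, 0.5, 0.5, 10))
  expect_equal(sum(ring2$grid & d2$mask$grid), 0)
  rows2 <- range(which(apply(ring2$grid[, , 1], 1, any)))
  rows1 <- range(which(apply(ring$grid[, , 1], 1, any)))
  expect_equal(diff(rows2) + 1, 2 * (diff(rows1) + 1), tolerance = 0.05)
})

test_that("rings clipped at the image border are flagged", {
  d <- make_disc_volume(n = 48, radius_px = 10, center = c(15, 5))
  ring <- perivascular_ring(d$mask, d$vol, ring_params(ring_distance = 10))
  expect_true("border_clipped" %in% attr(ring, "flags"))
  d_free <- make_disc_volume(n = 48, radius_px = 10)
  ring_free <- perivascular_ring(d_free$mask, d_free$vol,
                                 ring_params(ring_distance = 10))
  expect_false("border_clipped" %in% attr(ring_free, "flags"))
  expect_lt(sum(ring$grid), sum(ring_free$grid))
})

test_that("ring construction equals brute force on random anisotropic grids", {
  set.seed(42)
  for (i in 1:30) {
    nr <- sample(8:48, 1); nc <- sample(8:48, 1)
    sr <- sample(c(0.5, 0.7, 1, 1.25), 1)
    sc <- sample(c(0.5, 0.7, 1, 1.25), 1)
    m <- matrix(runif(nr * nc) < 0.06, nr, nc)
    if (!any(m)) m[sample(nr * nc, 1)] <- TRUE
    vol <- ct_volume(array(0, c(nr, nc, 1)), spacing = c(sr, sc, 5))
    ring <- perivascular_ring(seg_mask(array(m, c(nr, nc, 1))), vol,
                              ring_params(ring_distance = 5))
    expect_ring_matches_oracle(m, ring$grid[, , 1], sr, sc, 5)
  }
})

test_that("the fat window is inclusive at both bounds", {
  vox <- array(-1000, c(16, 16, 1))
  vox[8, 4:9, 1] <- c(-100, 10, -500, 0, -190, -190.0001)
  vol <- ct_volume(vox, spacing = c(1, 1, 5), validate = FALSE)
  rg <- array(FALSE, c(16, 16, 1)); rg[8, 4:9, 1] <- TRUE
  ring <- seg_mask(rg)
  attr(ring, "slice_range") <- 1L
  fat <- fat_mask(ring, vol)
  expect_identical(which(fat$grid[8, , 1]), c(4L, 7L, 8L)) # -100, 0, -190 in; 10, -500, -190.0001 out
})

test_that("widening the window never loses fat pixels", {
  ph <- test_phantom(noise_sd = 20, seed = 13)
  det <- detect_aorta_classical(ph$volume)
  ring <- perivascular_ring(det$mask, ph$volume)
  n_prev <- -1
  for (width in list(c(-120, -40), c(-160, -20), c(-190, 0), c(-400, 100))) {
    fat <- fat_mask(ring, ph$volume, ring_params(10, width[1], width[2]))
    expect_gte(sum(fat$grid), n_prev)
    n_prev <- sum(fat$grid)
  }
})

test_that("FAI is the pooled-pixel mean and the area formula is exact", {
  # three fat pixels across two slices: pooled mean, not mean of slice means
  vox <- array(200, c(8, 8, 2))
  vox[2, 2, 1] <- -100; vox[3, 3, 1] <- -50; vox[2, 2, 2] <- -60
  vol <- ct_volume(vox, spacing = c(0.7, 0.7, 5), validate = FALSE)
  fat <- seg_mask(vox < 0)
  attr(fat, "slice_range") <- 1:2
  res <- compute_fai(fat, vol)
  expect_equal(res$aa_fai, -70)              # (-100 - 50 - 60) / 3
  expect_equal(res$ct_pvat_area, 3 * 0.49 / 2)
  expect_equal(res$n_fat_pixels, 3)
  expect_equal(res$n_slices, 2)

  # 1000 fat pixels, 0.7 mm pixels, 2 slices -> 245 mm^2/slice
  vox2 <- array(-80, c(40, 40, 2))
  grid <- array(FALSE, c(40, 40, 2)); grid[seq_len(1000)] <- TRUE
  grid2 <- array(FALSE, c(40, 40, 2))
  grid2[, , 1] <- grid[, , 1]
  grid2[, , 2][seq_len(1000 - sum(grid[, , 1]))] <- TRUE
  stopifnot(sum(grid2) == 1000)
  fat2 <- seg_mask(grid2)
  attr(fat2, "slice_range") <- 1:2
  res2 <- compute_fai(fat2, ct_volume(vox2, spacing = c(0.7, 0.7, 5)))
  expect_equal(res2$ct_pvat_area, 245.0)

  # zero fat pixels: flagged, undefined FAI
  fat0 <- seg_mask(array(FALSE, c(8, 8, 2)))
  attr(fat0, "slice_range") <- 1:2
  res0 <- compute_fai(fat0, vol)
  expect_true("no_fat" %in% res0$flags)
  expect_true(is.na(res0$aa_fai))
})

test_that("noiseless phantoms are recovered exactly end-to-end", {
  ph <- test_phantom(seed = 19)
  det <- detect_aorta_classical(ph$volume)
  ring <- perivascular_ring(det$mask, ph$volume)
  fat <- fat_mask(ring, ph$volume)
  expect_identical(fat$grid, ph$truth$fat_index) # pixel-for-pixel
  res <- compute_fai(fat, ph$volume)
  expect_identical(res$aa_fai, ph$truth$fat_mean_hu)
  expect_identical(res$ct_pvat_area, ph$truth$fat_area_mm2_per_slice)

  # degenerate fat distribution: FAI exactly the constant
  phc <- make_phantom(phantom_spec(grid_shape = c(80, 80, 2), lumen_radius = 12,
                                   fat_hu_sd = 0, fat_hu_mean = -80, seed = 3))
  resc <- fai_pipeline(phc$volume)
  expect_identical(resc$aa_fai, -80)
})

test_that("whole-pixel translation leaves FAI and area unchanged", {
  base <- phantom_spec(grid_shape = c(96, 96, 2), lumen_radius = 12,
                       noise_sd = 0, seed = 23)
  ph <- make_phantom(base)
  shifted <- base
  shifted$center_path <- matrix(rep(c((96 - 1) / 2 + 4, (96 - 1) / 2 - 3),
                                    each = 2), ncol = 2)
  ph2 <- make_phantom(shifted)
  r1 <- fai_pipeline(ph$volume)
  r2 <- fai_pipeline(ph2$volume)
  # same seed, same candidate geometry up to translation: identical counts
  expect_equal(r1$n_ring_pixels, r2$n_ring_pixels)
  expect_equal(r1$n_fat_pixels, r2$n_fat_pixels)
  expect_identical(r1$aa_fai, r2$aa_fai)
  expect_identical(r1$ct_pvat_area, r2$ct_pvat_area)
})
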