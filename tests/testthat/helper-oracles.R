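# Independent brute-force oracles, kept deliberately naive.

# All-pairs squared Euclidean distance (mm^2) from every pixel center to the
# nearest TRUE pixel center, anisotropic spacing.
bf_edt2 <- function(mask, sr, sc) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (!nrow(idx)) return(out)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- min(sr^2 * (r - idx[, 1])^2 + sc^2 * (c - idx[, 2])^2)
  out
}

# Brute-force perivascular ring on one slice.
bf_ring <- function(mask, sr, sc, ring_mm) {
  d2 <- bf_edt2(mask, sr, sc)
  !mask & d2 <= ring_mm^2
}

# Exhaustive pair-count AUC: fraction of (positive, negative) pairs with
# score_pos > score_neg, ties counted 1/2.
bf_auc_paircount <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# Small default phantom used across tests: 80x80 px, 1 mm in-plane, 3 slices.
test_phantom <- function(..., seed = 11) {
  make_phantom(phantom_spec(grid_shape = c(80, 80, 3), lumen_radius = 12,
                            seed = seed, ...))
}

# Compare an implementation ring slice with the brute-force oracle, allowing
# disagreement only where the squared distance sits within float tolerance of
# the threshold (1-ulp envelope reordering with non-dyadic spacing).
expect_ring_matches_oracle <- function(mask_slice, ring_slice, sr, sc, ring_mm) {
  d2_bf <- bf_edt2(mask_slice, sr, sc)
  d2_impl <- aafai:::edt2_sq(mask_slice, sr, sc)
  fin <- is.finite(d2_bf)
  expect_true(all(abs(d2_impl[fin] - d2_bf[fin]) <=
                    1e-9 * pmax(1, d2_bf[fin])))
  oracle <- !mask_slice & d2_bf <= ring_mm^2
  decided <- abs(d2_bf - ring_mm^2) > 1e-6
  expect_identical(ring_slice[decided], oracle[decided])
}
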