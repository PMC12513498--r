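---
title: "Quantifying perivascular fat attenuation of the ascending aorta: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular fat attenuation of the ascending aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafai)
```

## The measurement

Inflamed adipose tissue is less lipid-rich and more aqueous than quiescent
fat, which shifts its CT attenuation upward (toward 0 HU). The fat
attenuation index (FAI) exploits this: it is the mean attenuation of the
adipose tissue immediately surrounding a vessel, and a higher (less
negative) FAI is read as a marker of perivascular inflammation. This package
implements the measurement for the ascending aorta (AA-FAI), together with
the perivascular adipose tissue area on CT (ct-PVAT area):

1. **Segment** the ascending aorta on each axial slice (built-in classical
   detector, or an externally supplied mask).
2. **Extent**: analyze a contiguous run of slices covering
   `extent_mm = 50` mm (5 cm) from the anchor slice, i.e.
   `ceiling(50 / slice_spacing)` slices.
3. **Ring**: per slice, collect pixels outside the vessel whose Euclidean
   distance to the nearest vessel pixel center is at most
   `ring_distance = 10` mm.
4. **Fat window**: keep ring pixels with attenuation in
   `[-190, 0]` HU, the CT range of adipose tissue.
5. **AA-FAI** is the *pooled-pixel* mean over all fat pixels of all
   analyzed slices (every pixel summed, divided by the pixel count — not a
   mean of per-slice means). **ct-PVAT area** is the total fat pixel area in
   mm&sup2; divided by the number of analyzed slices (mm&sup2;/slice).

```{r}
ph <- make_phantom(phantom_spec(seed = 7))
fai_pipeline(ph$volume)
```

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ring_distance` | 10 | mm | perivascular depot width used for aortic PVAT |
| `fat_hu_low`, `fat_hu_high` | −190, 0 | HU | CT range of fat; bounds inclusive |
| `extent_mm` | 50 | mm | ascending aorta up to 5 cm distal to the root |
| `lumen_hu_threshold` | 150 | HU | contrast-filled lumen is well above soft tissue |
| `radius_range` | 10–25 | mm | plausible adult ascending-aorta radii |
| `min_circularity` | 0.8 | — | the AA cross-section is nearly circular; rejects crescents/stripes |

The HU bounds are read as a closed interval: a pixel at exactly −190 HU or
exactly 0 HU is fat. Widening the window can therefore never lose fat
pixels, a property the test-suite asserts.

## Geometry: how the ring is built

The ring is constructed **per slice in 2-D**. Two considerations drove
this: the area is reported per slice, and at a typical 5 mm slice thickness
the through-plane voxel dimension is half the ring width, so a 3-D dilation
would smear the ring across slices whose vessel outline differs. In-plane
anisotropy *is* honored: distances are computed between pixel centers with
the true row/column spacing, using an exact anisotropic Euclidean distance
transform (a Felzenszwalb–Huttenlocher two-pass parabolic envelope,
implemented in C++). "Exact" is meant literally — the test-suite compares
the transform against a brute-force all-pairs scan on random grids and
requires agreement to within one floating-point ulp, and ring membership to
be identical away from the exact decision boundary.

The ring is measured outward from the **segmented vessel boundary**, and
vessel-interior pixels are never part of the ring or the fat mask. When the
segmentation is driven by lumen contrast, the thin aortic wall (soft-tissue
attenuation, outside the fat window) falls inside the ring but is excluded
by the HU window, so it cannot contaminate the FAI. No anatomical exclusion
beyond the HU window is applied; users with adjacent fat depots they wish
to exclude can supply an edited external mask.

Rings that would extend past the image are clipped and flagged
`border_clipped`; an empty mask slice is skipped and flagged; zero fat
pixels yields `aa_fai = NA` with the `no_fat` flag, and such cases are
excluded from cohort statistics rather than imputed.

## Segmentation

The built-in detector is deliberately classical: threshold at the lumen
attenuation, 4-connected components, keep components with equivalent radius
in `radius_range` and isoperimetric circularity ≥ `min_circularity`, track
across slices by nearest centroid (ties: higher circularity, then smaller
centroid row — fully deterministic), and fill holes in the selected
component. Circularity uses a Cauchy–Crofton-corrected perimeter (π/4 times
the exposed-edge length): the naive edge count overestimates a digital
circle's perimeter by 4/π, which would push a perfect disc's isoperimetric
quotient down to ≈0.62 and defeat the gate.

This detector is sufficient for contrast-like data with clean semantics and
is exercised exhaustively on phantoms; it is *not* a clinical segmenter. The
mask interface (`read_mask()`, label volumes or per-slice polygons
rasterized center-inside) accepts output from any external model, so a
learned segmenter can be dropped in without touching the quantification.

The analyzed extent is anchored at the first detected slice in ascending
slice order; an explicit `anchor` argument overrides this when the aortic
root is known from other information.

## The phantom generator

`make_phantom()` builds, per slice, a concentric structure: a contrast-bright
lumen disc (300 HU), a wall annulus (40 HU), and a surrounding region within
10 mm of the vessel in which a seeded random subset (`fat_fraction_of_ring`,
default 0.5) of pixels is fat and the rest soft tissue (50 HU), on an air
background (−1000 HU). Fat attenuation is drawn from a Gaussian
(default −80 ± 15 HU) truncated to the *open* interval (−190, 0), so a
ground-truth fat pixel can never be excluded by the closed-window test —
this is what makes the ground truth exact rather than approximate. Additive
Gaussian noise (`noise_sd`) is applied everywhere, after which voxels are
clamped to the physical CT range [−1100, 3200] HU.

The phantom's ground-truth aorta mask is the **lumen disc**: that is the
structure contrast delineates and the only boundary a threshold detector
(or a contrast-trained model) can recover; the wall annulus is
intentionally indistinguishable from soft tissue. The ground-truth fat
candidates are measured from that same lumen boundary with the same
center-to-center metric the pipeline uses, so on a noiseless phantom the
full pipeline returns the ground-truth fat mask pixel-for-pixel and the
ground-truth mean exactly. With noise, the pipeline FAI converges to the
ground-truth mean at the expected `noise_sd / sqrt(N)` rate, which the
suite verifies over 200 seeded phantoms at `noise_sd = 12` HU.

`quantize_hu = TRUE` rounds all values to integer HU so a phantom survives
DICOM integer storage bit-exactly; the ground truth records the quantized
values, keeping the exactness guarantee valid through a DICOM round trip.

What the phantom does **not** emulate: thoracic anatomy (lungs, pulmonary
artery, sternum, mediastinal fat contiguous with PVAT), beam hardening,
scanner-specific noise texture, or contrast-phase variation. Passing the
phantom suite therefore demonstrates the correctness of the geometry,
windowing and arithmetic — not clinical segmentation performance.

## The cohort simulator and ROC recovery

`simulate_fai_cohort()` draws per-group Gaussian AA-FAI values; the default
`study_groups()` are the published cohort summaries (non-HCTD −62.02 ± 8.54
HU, n = 159; Marfan syndrome −52.90 ± 12.69 HU, n = 36; Loeys–Dietz
syndrome −51.70 ± 7.99 HU, n = 9). Normality is an assumption — only means
and SDs are published — and every tolerance that depends on the simulated
cohorts inherits it.

`roc_analysis()` fixes the empirical-ROC semantics explicitly: candidate
cutoffs at midpoints between adjacent distinct scores plus ±∞; sensitivity
`P(score ≥ c | positive)` and specificity `P(score < c | negative)` with
the orientation *higher FAI = disease*; AUC by the trapezoidal rule (equal
to the Mann–Whitney pair statistic with ties counted ½ — asserted against
an exhaustive pair-count oracle and cross-checked against pROC); the Youden
cutoff maximizes `J = sens + spec − 1` with ties broken toward the smallest
cutoff. The AUC confidence interval is a seeded stratified percentile
bootstrap (2,000 replicates by default). The bootstrap is a methodological
substitute — the CI method behind the published interval is not stated —
and is documented as such, with its ~95 % coverage verified by simulation
against the closed-form binormal AUC.

`reproduce_study_roc()` repeats cohort → ROC over ≥500 replicates and
averages AUC, Youden cutoff, and sensitivity/specificity at a fixed
threshold (−55.3 HU). Under the default group summaries this recovers the
published discrimination: mean AUC ≈ 0.75 for HCTD vs non-HCTD and ≈ 0.72
for MFS vs non-HCTD, sensitivity ≈ 0.57 and specificity ≈ 0.79 at −55.3 HU,
and a mean Youden-optimal cutoff ≈ −54 HU — each computed at run time by
`scripts/acceptance.R` and the acceptance tests, not quoted from anywhere.

## Numerical and degenerate-input decisions

* Distances are compared as squared quantities against
  `ring_distance^2`; with non-dyadic spacings a pixel lying within one ulp
  of the boundary can differ from an independently rounded computation, so
  oracle tests treat only the open neighborhood of the boundary as
  undecided (no such pixel has been observed in practice).
* `welch_t()` accepts published summaries (mean, SD, n) as well as raw
  data; both paths use the Satterthwaite degrees of freedom and agree
  exactly on identical moments.
* Degenerate inputs fail loudly: one-class ROC, zero-variance correlation,
  non-positive heights/weights/diameters, phantoms whose fat mean sits
  outside (−190, 0) are all errors, not warnings.
* Missing comorbidity inputs yield `NA` ("undetermined") unless an observed
  criterion already decides the flag positively; a flag is `FALSE` only
  when every relevant input was observed and negative.
* All stochastic stages (phantom, cohort, bootstrap, replicate simulation)
  take explicit integer seeds; replicate streams are derived from a master
  seed by a fixed linear-congruential step, keeping every derived seed
  below 2³¹.

## Problem sizes

The shipped test-suite runs phantoms of 64–96 px in-plane and 2–3 slices,
110 random ring-oracle grids up to 48×48, 200 AUC-oracle instances up to
n = 50, 500 replicate cohorts per ROC contrast, and 500 simulated datasets
for bootstrap coverage — sizes chosen so the whole suite completes in well
under a minute on a single core while every guarantee is still exercised at
scale sufficient for its Monte-Carlo tolerance.

## Known limitations

* The classical detector assumes contrast-enhanced semantics; it will not
  find a non-contrast aorta, and its 100 % phantom success says nothing
  about recognition rates on clinical scans.
* The 10 mm ring is in-plane; through-plane partial-volume effects at 5 mm
  slices are not modeled.
* Per-patient FAI distributions are simulated as Gaussian; heavy tails or
  skew in real cohorts would perturb the simulated cutoff and
  sensitivity/specificity more than the AUC.
* No exclusion of non-fat anatomy beyond the HU window; contiguous
  mediastinal fat counts as PVAT unless masked out by the caller.
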