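Package: aafai
Title: Perivascular Fat Attenuation Index of the Ascending Aorta from CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies perivascular adipose tissue (PVAT) inflammation of
    the ascending aorta from contrast-enhanced chest CT. Builds a 10 mm
    perivascular ring around a segmented aorta using an exact anisotropic
    Euclidean distance transform, windows the ring to the CT fat range
    (-190 to 0 Hounsfield units), and reports the fat attenuation index
    (AA-FAI, pooled-pixel mean HU) and ct-PVAT area (mm^2 per slice).
    Includes CT volume and mask I/O (DICOM series, NIfTI, per-slice
    polygons), a classical threshold/circularity aorta detector with a
    pluggable external-mask mode, synthetic phantom and cohort generators
    with exact ground truth, clinical metrics (Mosteller body surface
    area, aortic size index, comorbidity and dilatation classification),
    and cohort statistics (Welch t, Pearson correlation, empirical ROC
    with bootstrap AUC confidence interval and Youden-optimal cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
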