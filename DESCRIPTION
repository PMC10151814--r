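Package: cmrqc
Title: Multilevel Quality Control of Cardiac MRI Short-Axis Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates paired expert/automatic contour annotations of cardiac
    magnetic resonance short-axis stacks. Computes clinical function parameters
    (end-diastolic and end-systolic volumes, ejection fraction for both
    ventricles, left ventricular myocardial mass) by disc summation over
    subpixel polygon contours; contour-level geometric agreement metrics
    (polygon-clipping Dice, boundary Hausdorff distance, per-slice volume
    differences); a multilevel error breakdown stratified by basal,
    midventricular and apical slice position with segmentation-decision
    precision and recall; and a statistical layer with paired t-tests, Fisher-z
    pooled correlations, ICC(3,1), Bland-Altman limits and equivalence testing
    against tolerance intervals. Ships a synthetic contour phantom generator
    with analytic ground truth and parametric reader-error models for
    validation, a documented JSON contour-stack interchange format, raster mask
    import/export, and a reporting driver producing the summary tables and
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    polyclip,
    rlang,
    sp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    png,
    RNifti,
    optparse,
    withr
Config/testthat/edition: 3
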