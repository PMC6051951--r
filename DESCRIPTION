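Package: petharm
Title: Harmonized Dual-Scanner Quantification of Iodine-124 PET and
    Two-Point Radioiodine Dosimetry Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparison of iodine-124 PET activity
    concentrations between scanner systems: post-reconstruction image
    harmonization (Gaussian resolution matching by quadrature, trilinear
    regridding to a common voxel grid, prompt-gamma-coincidence rescaling),
    spherical-VOI lesion quantification (max and 7-mm-sphere average activity
    concentration), and agreement analysis (percentage differences, Lin's
    concordance correlation with confidence interval and McBride class,
    Mann-Whitney subgroup tests, and a mean/SD acceptance rule). Includes a
    synthetic dual-scanner neck-lesion phantom generator for end-to-end
    validation, and a Monte-Carlo engine propagating activity-concentration
    uncertainty through the two-point mono-exponential model into the relative
    uncertainty of the projected iodine-131 time-integrated activity between
    24 and 120 h.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
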