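Package: gliopet
Title: PET/MRI Radiomics and Prognostic Modelling for High-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based 3D lesion segmentation and radiomic feature
    extraction for choline PET and contrast-enhanced MRI volumes of
    high-grade glioma, including SUV statistics (SUVmax, SUVmean, SUVpeak,
    MTV, TLA), the coefficient of variation as a heterogeneity marker,
    3D shape metrics (sphericity, surface, maximum diameter, spherical
    rim width), the peak-to-centroid distance family (SmCD, SpCD, MSR,
    nSpCD), and multifocal/multicentric lesion classification. Ships a
    synthetic phantom generator and a Weibull proportional-hazards cohort
    simulator with known ground truth, plus the downstream prognostic
    pipeline: feature correlation, median dichotomization, ROC cutoff
    selection, Kaplan-Meier/log-rank and Cox regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
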