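Package: speckpull
Title: Single-Aggregate Quantification and Biomarker Discovery for
    Inflammasome ASC Specks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule pull-down (SiMPull)
    imaging of inflammasome ASC specks and other protein aggregates in
    human biofluids.  Covers diffraction-limited spot counting per field
    of view with assay quality controls, super-resolution (dSTORM)
    localization-table processing (drift correction, histogram rendering,
    connected-component segmentation, area/perimeter/circularity
    morphometrics), two-group ECDF difference curves with
    Kolmogorov-Smirnov confidence bands and combined size/shape threshold
    discovery, cohort-level biomarker statistics (rank-based AUC, exact
    permutation tests, composite-biomarker enumeration, power analysis,
    assay precision), denaturation-stability curve fitting, and a
    synthetic-data generator that emulates blinking-fluorophore
    acquisitions and two-group patient cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
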