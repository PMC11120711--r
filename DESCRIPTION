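Package: elastoce
Title: Compression Optical Coherence Elastography Analysis of Tumor Stiffness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for phase-sensitive compression
    optical coherence elastography (C-OCE) of colorectal cancer tissue. Provides
    a speckle phantom generator with a calibrated reference silicone layer,
    phase-gradient ("vector" method) interframe strain estimation,
    pressure-standardized Young's modulus mapping, ROI stiffness quantification
    under a tumor-cell stiffness mask, cohort-level descriptive and inferential
    statistics (Mann-Whitney U with Bonferroni correction, Fisher's exact test),
    and ROC-based evaluation of stiffness thresholds as markers of KRAS/NRAS/BRAF
    driver mutations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    png
Config/testthat/edition: 3
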