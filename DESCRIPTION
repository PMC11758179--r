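Package: pexvote
Title: Threshold-Vote Biomarker Combinations from Plasma Exosome mRNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directional threshold-vote marker combinations from
    qPCR delta-Ct plasma exosome mRNA panels and the neutrophil-to-lymphocyte
    ratio, ranks them by ROC AUC with DeLong confidence intervals, freezes the
    best-performing score for prognostic stratification (Kaplan-Meier,
    log-rank, Cox hazard ratios), and correlates frozen plasma markers with
    tumor immune-microenvironment readouts in a paired cohort. Ships a
    synthetic-cohort generator so every stage of the pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
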