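Package: teacqsar
Title: TEAC Antioxidant Screening and GA-MLR QSAR Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the radical-scavenging activity of drug-like
    compounds as TROLOX-equivalent antioxidant capacity (TEAC) from HPLC-DPPH
    peak areas, and for building and validating multiple-linear-regression
    QSAR models that predict TEAC from normalized molecular descriptors.
    Includes TROLOX calibration and method-verification statistics, activity
    banding, min-max descriptor normalization, rational activity-ranked
    train/test splitting, genetic-algorithm descriptor-subset selection with
    QUIK-rule redundancy filtering (multivariate K correlation index), a full
    internal/external validation suite (Q2 leave-one-out and leave-many-out,
    Q2 F1/F2/F3, Lin's concordance correlation, PRESS, Y-scrambling), a
    leverage-based applicability domain with Williams plots, a set of eight
    fixed published TEAC regression equations, and a synthetic descriptor-data
    generator for end-to-end testing of the whole workflow.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
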