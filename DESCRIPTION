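Package: qsarmlr
Title: Multiple Linear Regression QSAR Modelling with Leave-One-Out,
    Y-Randomization and Applicability-Domain Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates multiple linear regression (MLR)
    quantitative structure-activity relationship (QSAR) models from tables
    of molecular descriptors and pIC50 activities. Provides ordinary
    least-squares fitting via Householder QR with hat-matrix leverages, the
    classical QSAR validation statistics (R2, adjusted R2, standard error of
    estimate, Fisher ratio, quality factor, probable error, PRESS/SSY),
    exact leave-one-out cross-validation with the hat-diagonal shortcut,
    Y-randomization (activity scrambling) robustness testing with the cRp2
    chance-correlation metric, a leverage-based applicability domain with
    Williams-plot output, conceptual-DFT global reactivity descriptors from
    frontier-orbital energies, candidate-compound screening, and a
    synthetic-data generator for parameter-recovery studies. Ships a
    27-compound benzylidene-thiazolidinedione PTP1B inhibitor training set
    as a plain-text fixture.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
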