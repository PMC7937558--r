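Package: cagecog
Title: Automated Home-Cage Behavioral Phenotyping and Genotype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping mice from automated home-cage event logs
    (corner visits, nose-pokes, licks) and classifying wild-type versus
    App knock-in (Alzheimer's-model) genotypes from the derived behavioral
    parameters. Implements the canonical 60-parameter feature schema across
    place preference, reversal, serial reaction time, place avoidance and
    delay-discounting tasks; per-feature genotype t statistics; a small
    feed-forward network classifier and a univariate threshold-vote control
    classifier; cross-validated stepwise forward feature selection with an
    optional nested (selection-inside-folds) evaluation; and a synthetic
    cohort generator, at event and feature level, with planted genotype
    effects for calibration and power checks.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    yaml
Config/testthat/edition: 3
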