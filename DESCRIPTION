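Package: exposcreen
Title: Non-Targeted Suspect Screening of Environmental Chemical Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for non-targeted LC-QTOF/MS suspect
    screening of environmental chemical exposures in paired maternal and
    umbilical-cord serum. Implements water-blank filtering, formula matching by
    mass accuracy, duplicate feature collapsing within and across batches and
    ionization modes, isomer annotation scoring from literature and production
    evidence, propensity-score matched differential detection testing with
    empirical-Bayes batch correction, silicone-wristband cross-platform
    comparison, and correlation with tract-level geographic pollution scores.
    Includes a synthetic-data generator with known ground truth that emulates a
    two-city pregnancy cohort study, so every stage is testable end to end
    without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
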