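Package: fadseed
Title: Seed Spot-Cover Morphometrics and Fitness-Associated Dispersal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fitness-associated dispersal in myrmecochorous
    plants through the seed spot-cover phenotype. Segments seed photographs
    into seed-body, pigmentation-spot and elaiosome layers and computes
    percent spot cover; aggregates seed measurements to plant level with a
    flower-count fitness proxy and rank-based seed categorization; fits the
    plant-level and seed-level fitness-phenotype regressions; estimates
    germination curves (inverse Kaplan-Meier) with rank-sum and log-rank
    comparisons; and analyses paired-choice and checkerboard-grid ant
    seed-removal assays. A synthetic-data module generates seed images with
    ground-truth masks, fitness-correlated plant populations, germination
    tables and removal logs for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    png,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
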