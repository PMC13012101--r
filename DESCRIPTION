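Package: pasnet
Title: Proteostasis Network Activity Scoring, Target Prioritization and
    Drug-Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles a focal-protein proteostasis network from functional
    interactions and consensus relative-expression perturbation across
    case/control cohorts, computes the proteostasis activity score (PAS) and
    treatment-induced changes in it (delta-PAS), ranks network proteins by
    heat-diffusion and personalized-PageRank influence, fits a shrinkage
    Gaussian graphical model of the network on single-cell expression and
    simulates knockdown/overexpression through the resulting linear model,
    and classifies dose-dependent drug effects on network activity across
    cell lines. Ships seeded synthetic-data generators with planted ground
    truth for every pipeline input, so each stage is testable end to end.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
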