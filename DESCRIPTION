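Package: flpscape
Title: Evolution of Female-Limited Plumage Polymorphism on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@flpscape.org", role = c("aut", "cre"))
Description: Tools to quantify and analyse female-limited plumage polymorphism
    (FLP), the co-occurrence of male-like (androchrome) and distinct
    (heterochrome) female morphs within bird species, with hummingbirds as the
    motivating radiation. Provides ordinal specimen scoring models with
    heterochrome/androchrome binarisation, Hartigan's dip statistic with
    bootstrap calibration for detecting bimodal female scores,
    presence/absence decision rules with detection-probability design
    calculations and sensitivity grids, three-state Mk models (equal-rates,
    symmetric, all-rates-different) with small-sample AICc selection, marginal
    ancestral-state reconstruction and independent-origin counts,
    discriminant-based androchromy scoring from plumage patch colours with
    morphometric regressions and Blomberg's K, phylogenetic generalised least
    squares for socioecological correlates, and a fully seeded synthetic-data
    generator so the complete pipeline can be exercised and calibrated without
    museum specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    expm,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    nlme,
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
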