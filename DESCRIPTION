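Package: instaflux
Title: Instationary 13C Metabolic Flux Analysis for Methylotrophic Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for instationary 13C metabolic flux analysis (INST-13C-MFA)
    of microbial central carbon metabolism, built around the co-assimilation of
    glucose and methanol by Pichia pastoris in chemostat culture. The package
    parses atom-transition network definitions, decomposes them into elementary
    metabolite units (EMUs), simulates transient and steady-state mass-isotopomer
    distributions by stiff ODE integration, fits free fluxes and unmeasured pool
    sizes to labeling time courses by weighted least squares with chi-square
    goodness-of-fit testing and linearized confidence intervals, checks the
    second-law consistency of metabolite concentrations against assumed flux
    directions (network-embedded thermodynamic analysis), and reconstructs
    macroscopic carbon, redox and ATP balances from a fitted flux distribution.
    A synthetic-data module generates seeded ground-truth fluxes, pool sizes and
    noisy measurement tables with the statistical structure of a labeling
    wash-in experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
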