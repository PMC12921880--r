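Package: dcfbiodeg
Title: Degradation Kinetics, Ecotoxicity and Community-Shift Analysis for
    Diclofenac Biodegradation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for bench-scale pharmaceutical
    biodegradation experiments, with diclofenac (DCF) as the reference
    compound. Fits Simple First-Order (SFO) and biphasic Hockey-Stick (HS)
    decay models to concentration time series with FOCUS-style chi-squared
    error assessment and DT50 half-lives; estimates growth-inhibition IC50
    from quadratic log-dose viability regressions; computes bioluminescence
    EC50, Toxic Units and Persoone hazard classes from Microtox-style
    dilution series; summarises metabolite time courses; and summarises
    before/after microbial community shifts (rarefaction, alpha diversity,
    genus composition, ASV overlap) from amplicon count tables. Seeded
    synthetic-data generators emulate each assay so the whole pipeline is
    testable without laboratory data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
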