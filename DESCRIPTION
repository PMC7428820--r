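Package: cloneforecast
Title: Spatial Tumour Clonal Evolution and Outcome Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic spatial simulation of tumour growth and clonal
    evolution on a two-dimensional deme lattice (exact Gillespie dynamics
    with driver and resistance mutations, crowding-regulated deme
    populations and calibrated cell dispersal), together with the
    downstream analysis pipeline: virtual-biopsy and edge sampling of
    clone counts, inverse Simpson clonal diversity, clonal turnover,
    cohort-level forecasting of future tumour growth rate by rank
    correlation, and progression-free survival analysis after simulated
    treatment (Kaplan-Meier, log-rank, Cox proportional hazards with
    martingale-residual transform selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
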