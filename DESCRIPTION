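Package: rivermet
Title: River Metabolism Estimation from Diel Dissolved-Oxygen Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates daily gross primary productivity (GPP), ecosystem
    respiration (ER), and the gas-exchange rate constant (K600) in rivers
    from 15-minute dissolved-oxygen time series using a one-station
    oxygen mass-balance state-space model with Bayesian partial pooling
    of ln(K600) on ln(discharge). Includes preparation of model inputs
    (regridding, gap filling, solar time, oxygen saturation, clear-sky
    light), linear stage-rating and hydraulic-geometry estimation of
    river depth and velocity, a synthetic diel-oxygen generator for
    testing parameter recovery, and the quality-assurance workflow of
    daily flags, censoring, metabolism reach-length screening, and
    site-level confidence ratings used for the Illinois River Basin
    metabolism data release (doi:10.5066/P9TEBOUR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
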