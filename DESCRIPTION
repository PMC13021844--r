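Package: rxits
Title: Interrupted Time Series Analysis of Drug Dispensing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pharmacoepidemiological interrupted time series (ITS)
    analysis of monthly drug dispensing registries. Computes standard drug
    utilization outcomes (dispensed DDD per 1000 inhabitants per day, incident
    recipients per 100,000 with a 12-month washout), builds pandemic
    intervention regressors (a March-May 2020 stockpiling pulse, post-June-2020
    ramps with an optional end-2021 plateau), fits seasonal ARIMA models with
    external regressors, runs Ljung-Box and KPSS residual diagnostics, and
    converts fitted coefficients into cumulative pandemic-attribution
    estimates with middle/low/high bounds and shares of the observed value.
    A stratified synthetic-data generator emulates registry dispensing series
    so the whole pipeline is testable without access to person-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
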