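Package: amucost
Title: Costing Antimicrobial Use in Small-Scale Chicken Flocks
Version: 0.1.0
Authors@R:
    person("AMU", "Surveillance Tools", email = "amucost@example.org",
           role = c("aut", "cre"))
Description: Tools to standardize retail prices of veterinary antimicrobial
    products to the animal daily dose for a 1 kg bird (ADDkg), classify
    products by WHO criticality of their active ingredients, aggregate
    flock-diary records into weekly use-probability and expense series
    stratified by disease and mortality, and fit farm-random-intercept
    linear models of price determinants with forward stepwise selection.
    Includes a calibrated synthetic generator of product catalogues, price
    records and flock diaries so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
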