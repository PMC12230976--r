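Package: migmort
Title: Migration-Status Mortality Analysis for Register-Style Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying internal-migration mortality differentials from
    register-style individual histories. Simulates residential and mortality
    histories under a census-then-annual observation scheme, classifies
    individuals into stayers, leavers, and returnees (with age-at-migration
    bands), imputes left- and interval-censored ages at migration from a
    piecewise-constant-hazard model, aggregates deaths and person-years into
    exposure tables with proportional redistribution of ill-defined causes of
    death, fits negative-binomial generalized additive mortality models with
    status-specific smooth age effects, converts fits into average marginal
    rates and rate ratios with simulation-based percentile intervals, builds
    partial life tables and temporary life expectancies for ages 20-95, and
    decomposes longevity gaps by age and cause with the line-integral
    (Horiuchi) method.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mgcv,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
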