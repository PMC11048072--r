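Package: chomet
Title: Stoichiometric and Kinetic Modelling of CHO Fed-Batch Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing central carbon metabolism of Chinese hamster
    ovary (CHO) cells in standard and high-seeding-density fed-batch cultures.
    Provides a curated central-carbon stoichiometric network with flux balance
    analysis (FBA) and metabolic flux analysis (MFA), pre-processing of offline
    culture measurements into cell-specific rates (outlier screening, LOWESS
    smoothing, fed-batch mass balances), a reduced kinetic ODE model of the
    lactate production-to-consumption shift with asparagine-coupled regulation,
    ensemble model calibration with AIC-based structure selection and
    viable-parameter-space sampling, feed-composition simulation studies, and a
    synthetic fed-batch data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quadprog,
    deSolve,
    lhs,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Matrix,
    knitr
Config/testthat/edition: 3
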