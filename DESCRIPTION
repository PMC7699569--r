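Package: marspanel
Title: Multivariate Adaptive Regression Splines and Causality Screens for
    Balanced Country-Year Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A from-scratch Multivariate Adaptive Regression Splines (MARS)
    engine -- hinge basis functions with knots at observed values, greedy
    forward pair addition, generalized cross-validation (GCV) backward
    pruning, and subset-based variable importance -- together with the
    econometric screens that precede spline modelling of life-expectancy
    determinants on macro panels: exactly-identified two-stage least
    squares, the Hausman endogeneity test, and the stacked
    (common-coefficient) panel Granger causality test. Includes a balanced
    wide-format panel data model with CSV input/output and synthetic-data
    generators that emulate a 14-country by 23-year European panel of
    life expectancy and its socioeconomic covariates, so the full analysis
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
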