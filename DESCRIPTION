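Package: heatlag
Title: Distributed-Lag Nonlinear Temperature-Mortality Analysis for Tropical Daily Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling short-term associations between daily mean
    temperature and mortality counts in tropical cities with narrow
    temperature ranges. Implements exposure-lag-response cross-bases built
    from natural cubic splines and hockey-stick (single- and double-threshold)
    predictor bases, quasi-Poisson time-series regression with seasonal trend,
    humidity, day-of-week and holiday controls, delta-method relative-risk
    curves with minimum-mortality-temperature extraction, an objective
    model-simplification procedure (spline to double-threshold to
    single-high-threshold), season-specific log-mortality models, and a
    calibrated synthetic-data generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    splines
Config/testthat/edition: 3
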