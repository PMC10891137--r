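Package: lucsim
Title: Land-Use Change Simulation with Suitability Modelling and
    Demand-Constrained Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage workflow for forecasting categorical land-use/
    land-cover (LULC) maps: a multinomial suitability classifier trained on
    multi-temporal maps and environmental predictors (with balanced sampling
    of the rare changing cells and SMOTE-NC oversampling of minority classes),
    linear demand extrapolation with policy overrides, time-varying binary
    transition rules, and iterative CLUE-S allocation that balances per-cell
    suitability against per-class demand under those rules.  Includes a
    synthetic-landscape generator with known dynamics for end-to-end testing,
    plain-text raster input/output, and the map-comparison statistics
    (overall accuracy with confidence interval, quantity and allocation
    disagreement, per-class sensitivity, specificity and balanced accuracy)
    used to validate such forecasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
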