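Package: riceNsat
Title: Saturation-Aware Nitrogen Status Diagnostics for Rice from
    Leaf-Clip Optical Sensor Readings
Version: 0.1.0
Authors@R:
    person("riceNsat", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing rice nitrogen status from Dualex-type
    leaf-clip sensor readings (chlorophyll, flavonoid and nitrogen balance
    indices measured on the top five leaves). Implements critical nitrogen
    dilution-curve fitting and the Nitrogen Nutrition Index (NNI), an
    incremental rate-of-change analysis with kernel-density peak detection
    that quantifies sensor saturation at high nitrogen supply, a
    multi-model regression benchmark (linear, quadratic, partial least
    squares, support vector, random forest, gradient boosting and neural
    network regressors) under 10-fold cross-validation, and exact
    interventional Shapley attributions for the tree ensembles. A
    synthetic field-trial generator with known ground truth makes every
    stage testable without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
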