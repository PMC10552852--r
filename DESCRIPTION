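Package: concresp
Title: Concentration-Response Curve Processing for High-Throughput Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bidirectional concentration-response modelling for medium- and
    high-throughput in vitro screening data. Fits ten parametric models
    (constant, linear and quadratic polynomial, power, Hill, gain-loss, and
    four exponential forms) under a robust Student-t likelihood, selects a
    winning model by AIC, computes a continuous hit call as the product of
    three confidence weights, derives potency estimates (AC50, AC10, AC5,
    AC95, ACB, ACC) and a benchmark dose with a 90 percent
    profile-likelihood confidence interval, assigns hierarchical fit
    categories and cautionary flags, and computes per-chemical cytotoxicity
    burst thresholds. Includes a synthetic-data generator with known ground
    truth and a flat-file pipeline over long-format assay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
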