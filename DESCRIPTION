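Package: ttesim
Title: Target Trial Emulation and Longitudinal G-Methods for Simulated
    Hospital Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates daily-resolution hospitalized cohorts with
    treatment-confounder feedback and known counterfactual truth, and
    estimates 28-day counterfactual mortality under dynamic corticosteroid
    regimes by longitudinal g-computation, inverse probability weighting,
    and a sequentially doubly robust (SDR) estimator with super-learner
    ensembling and cross-fitting.  Also constructs the ten "model-first"
    Cox study designs commonly seen in the observational corticosteroid
    literature so that immortal-time and related design biases can be
    demonstrated against the known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    xgboost,
    FNN,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
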