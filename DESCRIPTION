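Package: warfinr
Title: Individualized Warfarin Dosing from Longitudinal INR Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the next-visit international normalized ratio (INR) of
    patients on warfarin from fixed clinical and pharmacogenetic covariates
    (CYP2C9 and VKORC1 genotypes, age, body size, amiodarone use) combined
    with the time series of prior doses, observed INRs and visit intervals.
    The predictor is a hybrid network: a feedforward branch embeds the fixed
    covariates and a long short-term memory (LSTM) branch processes the visit
    sequence; the two are fused at every timestep to emit one next-INR
    prediction per visit transition.  On top of the predictor the package
    provides dose recommendation by inversion over the discrete grid of
    quarter-tablet warfarin doses, banded prediction-accuracy evaluation with
    follow-up-window and genotype-responder breakdowns, Rosendaal time in
    therapeutic range, and a mechanistic turnover simulator that generates
    realistic longitudinal anticoagulation cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
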