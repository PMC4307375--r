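Package: rrbridge
Title: Bayesian Bridging Prediction of Clinical Rate Ratios from Biomarker
    Summary Data
Version: 0.1.0
Authors@R:
    person("rrbridge", "maintainers", email = "rrbridge@example.org",
           role = c("aut", "cre"))
Description: Builds a trial-level Bayesian meta-analytic association model
    between a dichotomous biomarker (e.g. virus infection) and a dichotomous
    clinical endpoint (e.g. disease), using only per-arm responder counts from
    historical randomized trials. The fitted model predicts the clinical rate
    ratio -- and hence vaccine efficacy VE = 1 - RR -- of a new trial from its
    observed biomarker counts alone, with a median point estimate and a 95%
    percentile credible interval from MCMC. A patient-level simulation engine
    driven by the biomarker's positive and negative predictive values (PPV,
    NPV) evaluates predictive ability (modified bias, modified RMSE, average
    credible-interval width on the ratio scale) across link functions, trial
    counts and association strengths, and applicability rules (PPV/NPV >= 0.5
    for equal values; PPV + NPV >= 1 for high-NPV biomarkers) are reported
    alongside predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
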