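Package: dietvalid
Title: Measurement Error Models for Dietary Validation Studies with
    Recovery Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating self-report dietary assessment
    instruments (online and interviewer-administered 24-hour recalls)
    against recovery and predictive nutritional biomarkers.  Implements a
    three-instrument latent true-intake measurement error model fitted by
    full-information maximum likelihood with missing-at-random data,
    attenuation factors and correlations with true intake for single and
    repeated administrations, closed-form extrapolation of validity
    metrics to k repeat administrations, biomarker construction from
    24-hour urine collections (urinary nitrogen, potassium, sucrose plus
    fructose with age/sex calibration, PABA completeness checks) and
    energy expenditure records, and a synthetic cohort generator with the
    exact statistical structure the model assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
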