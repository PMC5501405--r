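Package: inhalerdce
Title: Discrete Choice Experiments for Inhaler Device Preferences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing discrete choice experiments
    (DCEs) on dry-powder inhaler device preferences. Generates D-efficient
    blocked fractional-factorial choice designs by coordinate exchange,
    simulates study-like respondent cohorts and two-step choice/ranking
    responses under a rank-ordered logit random-utility model, fits the
    rank-ordered (exploded) logit with a patient-level random effect on the
    status-quo alternative by maximum likelihood with Gauss-Hermite
    quadrature, and infers willingness to pay (WTP) for attribute changes
    with Metropolis MCMC credibility intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
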