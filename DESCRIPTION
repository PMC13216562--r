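Package: truthsdt
Title: Signal-Detection Analysis of Truth Judgments and Misinformation Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores binary truth judgments of true and false claims into the three
    signal-detection components of misinformation susceptibility: truth sensitivity
    (d-prime), acceptance threshold (criterion c), and myside bias (the criterion
    difference between belief-incongruent and belief-congruent claims). Provides
    extreme-rate correction, odd/even split-half scoring, scoring of a 15-measure
    individual-difference battery with Cronbach's alpha, split-half multiple
    regressions predicting false-alarm rates, correlation screens with partial
    correlations and Holm adjustment, a bifactor structural model relating a general
    reflective-open-mindedness factor and specific factors to split-half truth
    sensitivity, and a synthetic-cohort generator under an equal-variance Gaussian
    model so that every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
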