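Package: pathies
Title: Prognostic Validation of IHC4 and Clinical Risk Scores for Late
    Distant Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the IHC4 immunohistochemical prognostic score, the
    accompanying clinical score, their combination (IHC4+C) and the refitted
    IHC4+Clinical PathIES score for postmenopausal ER-positive breast cancer
    cohorts, and validates their prognostic value for time to distant
    recurrence: quartile risk-group stratification, Kaplan-Meier and log-rank
    comparisons, Cox proportional hazards models with forced-treatment
    backward selection, treatment-by-risk-group interaction testing, and
    calibration of predicted 10-year distant-recurrence probabilities by
    score decile. Ships a synthetic survival-cohort generator calibrated to
    published cohort descriptors so every pipeline stage is testable with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
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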