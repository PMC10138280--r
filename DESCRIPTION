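Package: stepscore
Title: Performance Scoring for Clinical Stress Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns a performance-scoring function for stress-test set-ups
    from pairwise ordering constraints: a clinical severity ordering between
    subjects, a difficulty ordering within subjects, and a low-variance
    constraint on repeated trials.  The score is fitted either by gradient
    boosting of shallow regression trees with a Huber-smoothed hinge
    objective, or as a linear model by Newton-Raphson.  Per-difficulty scores
    are aggregated into a single reserve-capacity index by distance from a
    healthy-reference plane.  Includes a synthetic-cohort simulator, ordered
    set construction, concordance and ROC-based evaluation (bootstrap
    confidence intervals, DeLong comparison, harmonic-mean p-value), and a
    simulation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
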