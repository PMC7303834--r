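Package: dranet
Title: Distributed Regression Analysis for Horizontally Partitioned Data Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear, logistic, and Cox proportional hazards regression
    models across horizontally partitioned data networks without pooling
    individual-level records. Each data-partner site computes summary-level
    intermediate statistics (sums-of-squares-and-cross-products matrices,
    score vectors and information matrices, per-event-time risk-set sums)
    that an analysis center aggregates and iterates on, yielding estimates,
    standard errors, model fit statistics, and privacy-preserving
    diagnostics (binned ROC curves, Hosmer-Lemeshow calibration, baseline
    survival) that agree with the pooled individual-level analysis to
    machine precision. Includes a file-based master-worker exchange
    protocol with trigger files and per-step timing instrumentation, a
    synthetic bariatric-style cohort generator with known truth, and
    pooled-reference difference reports for equivalence verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
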