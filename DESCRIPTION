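Package: ipvi
Title: Inverted-Pendulum Validity Index for Quiet-Standing Posturography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well the single-link inverted-pendulum
    model describes quiet standing from force-platform recordings. Reconstructs
    the anterior-posterior centre-of-mass trajectory from centre-of-pressure and
    horizontal ground-reaction-force signals by zero-point-to-zero-point double
    integration, computes the inverted-pendulum validity index (the Pearson
    correlation between the COP error and the AP ground-reaction force) together
    with conventional sway-velocity measures, and provides windowed, trial-averaged
    and group-comparison analyses (Student's t-tests, ROC/AUC, threshold accuracy).
    Includes seeded single-link and two-link (ankle-hip) quiet-stance simulators
    that emit COP, GRF and ground-truth COM so the whole pipeline can be validated
    without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
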