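Package: tsgrtd
Title: Semi-Mechanistic Residence-Time Moments for Twin-Screw Wet Granulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the central moments of the residence time distribution
    (mean residence time and normalized variance) in twin-screw wet
    granulation from screw geometry and operating conditions. Implements
    reduced-order holdup, flow and mixing factors built from available
    screw-section volumes, a Peclet-number model under the open-open
    dispersion boundary condition, dimensional-consistency constraints on
    the tuning exponents, and a seeded k-fold cross-validated constrained
    least-squares fitting pipeline, together with a design-of-experiments
    synthetic data generator, main-effects and parity reporting, and CSV
    dataset input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
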