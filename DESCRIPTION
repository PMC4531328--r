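Package: rbelet
Title: Energy-Transfer Efficiency Modelling of Ion-Beam Relative
    Biological Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts relative biological effectiveness (RBE) of protons and
    heavier ions from ion charge Z, linear energy transfer (LET), dose or
    surviving fraction, and the low-LET linear-quadratic radiosensitivities
    alpha and beta. Implements saturation relations linking Z to the
    LET-RBE turnover point and low-LET radiosensitivities to their maxima,
    piecewise efficiency scaling of alpha and beta with LET, iso-effect
    solving of the linear-quadratic equation for RBE as a function of dose
    or survival level, biologically-effective-dose (BED) iso-effect
    calculations across fractionation schedules, deterministic
    least-squares calibration of the saturation relations and of
    clonogenic survival curves, and a seeded synthetic survival-data
    generator. A command-line interface exposes every calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
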