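Package: mltsys
Title: Two-Parameter Model Life Table Systems and Estimation-Bias Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and calibration of two-parameter model life table
    systems on abridged (20-age-group) mortality schedules: a log-quadratic
    system with an SVD shape component, a Brass-type modified-logit relational
    system with child and adult correction factors, and a discrete-family /
    continuous-level system fitted by model-based clustering.  Includes full
    abridged life table machinery (mx, qx, lx, Lx, Tx, ex with injectable
    separation factors), indicator extraction (1q0, 5q0, 45q15, 20q60, e0),
    an evaluation pipeline computing residuals, average relative errors,
    residual-sign bias classes and compound mortality-decline trend
    statistics, a 45q15-range envelope diagnostic, and synthetic-data
    generators for calibration corpora and China-like observed series so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
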