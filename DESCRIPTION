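Package: lymphodyn
Title: Malignant B-Cell Population Dynamics Under Combination Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Parametric modelling of malignant B-cell population dynamics
    in a SCID-mouse lymphoma xenograft under antisense-bcl-2, anti-CD-20
    (rituximab) and combination therapy. Implements a nondimensional
    logistic-type growth model with crowding-enhanced cell death and
    direct antibody kill, a four-step calibration strategy that fits the
    control and single-agent arms and predicts the combination arm with
    no additional parameters, derived cell-lifetime and synergy-ratio
    reports, a synthetic tumor-volume cohort generator, and a small
    command-line pipeline over CSV input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
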