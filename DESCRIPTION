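Package: turndetect
Title: Real-Time Detection of Turns During Gait from Wearable Inertial
    Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the onset, direction and amplitude of walking turns in
    real time from a single body-worn inertial measurement unit. A
    dual-threshold rule on vertical-axis angular velocity and orientation
    declares turn onset; the two thresholds are trained by minimising an
    error-counting cost over a database of labelled trials with a seeded
    population-based optimiser; turn direction (left/right) and amplitude
    (22/45/90 degrees) are classified with a linear discriminant on a
    three-signal snapshot taken shortly after onset. Includes the full
    evaluation protocol (within-subject and subject-independent
    leave-one-out crossvalidation with correct/premature-late/missed
    detection and false-positive rates), a synthetic gait-trial generator
    emulating the measurement protocol with a top-down turning strategy and
    a slow-turning amputee profile, CSV/JSON trial persistence, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
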