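Package: megelm
Title: Interictal MEG Classification with Random-Mapping Ensemble Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating healthy, generalized-epileptic
    and focal-epileptic subjects from resting-state interictal
    magnetoencephalography (MEG). Provides KPSS-based selection of stationary
    segments, per-segment spectral features (total and relative band power on
    2-Hz bands spanning 4-40 Hz) and phase-synchronization features
    (phase-locking value and phase-lag index with proportional thresholding),
    an extreme-learning-machine ensemble classifier with a least-squares
    readout and majority voting, subject-wise leave-one-out cross-validation,
    and a two-stage cascade that assigns one of three diagnostic labels per
    subject. A synthetic-cohort generator with planted band-power and
    phase-coupling contrasts makes the full pipeline testable without access
    to clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
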