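Package: qtsilico
Title: In Silico Proarrhythmia Assessment with Translational PKPD
    Reclassification for QTc Liability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples a population of O'Hara-Rudy human ventricular
    action-potential models under Hill pore-block ion-channel pharmacology
    with an M5 pruned model-tree translational PKPD regression to predict
    QTc-interval prolongation in the anesthetized guinea-pig assay.
    Provides action-potential and calcium-transient biomarker extraction
    (APD, CTD, the electromechanical window and abnormality flags),
    hERG safety-margin and in-silico directional classification rules with
    tPKPD-based reclassification, confusion-matrix metrics with Wilson
    score intervals, packaged compound potency and outcome tables, and
    seeded synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
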