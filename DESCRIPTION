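Package: drugsens
Title: Drug Sensitivity Scoring, Target Addiction and Synergy Analysis
    for High-Throughput Viability Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plate-based drug sensitivity screens of
    B-cell malignancy models: control-based normalization of luminescent
    viability readouts, four-parameter logistic dose-response fitting, a
    modified DSS3 drug sensitivity score, target addiction scoring over
    drug-target annotations, Bliss independence synergy scoring of
    combination matrices and 1:1 diagonal designs, a count-based
    CPM/MC/L2FC differential-transcription filter for paired
    parental/resistant cell lines, deterministic flow-cytometry MFI
    transforms, and synthetic-data generators that emulate each assay so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
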