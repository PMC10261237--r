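Package: mpxcutoff
Title: Cutoff Estimation for a Binary Multiplex PCR Validated Against
    Quantitative BCR::ABL1 qRT-PCR
Version: 0.1.0
Authors@R:
    person("mpxcutoff", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate prognostically relevant percent
    international scale (%IS) cutoff values for a qualitative multiplex
    PCR assay detecting BCR::ABL1 fusion transcripts, validated against
    quantitative TaqMan qRT-PCR in chronic myeloid leukemia molecular
    monitoring. Implements qPCR standard-curve calibration and
    copy-number quantification, gel band-size classification of fusion
    transcript variants, an inverted sensitivity/specificity cutoff
    sweep with ROC construction and DeLong AUC confidence intervals,
    Youden-optimal cutoff selection, a seeded synthetic cohort generator
    with a logistic limit-of-detection model, cohort summary tables and
    a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
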