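Package: nelfayap
Title: NELFA-YAP Co-Regulation, Promoter-Proximal Pausing and Clinical
    Stratification Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for studying how the NELF-mediated
    promoter-proximal pausing checkpoint constrains YAP-driven
    transcription.  Implements a four-condition knockdown
    differential-expression stage, the four-category NELFA x YAP
    co-regulation classifier with Venn/UpSet overlap accounting,
    pre-ranked gene-set enrichment (ES/NES with a gene-sampling null)
    and Fisher-exact transcription-factor target overlap statistics,
    promoter-window and gene-body quantification of ChIP and nascent
    transcription tracks with a coordinated-loss caller, and clinical
    immunohistochemistry scoring with ROC dichotomization,
    Kaplan-Meier/log-rank survival and contingency testing.  A
    synthetic-data module generates negative-binomial count matrices,
    promoter-peaked signal tracks and survival cohorts with known truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    survival,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
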