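Package: circlr
Title: Desk-Scale Circular RNA Discovery, Quantification and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for circular RNA (circRNA) analysis on
    synthetic data with known ground truth: paired-end read simulation with
    RNase R enrichment, de novo backsplice-junction (BSJ) discovery by
    anchor-based and annotation-guided detectors, junction-contig
    quantification with circular-to-linear ratios (CLR) and global
    circularization metrics, simplified negative-binomial Wald differential
    expression with Benjamini-Hochberg control, and dual-rank (information
    gain + forest importance) feature selection feeding an SVM classifier
    evaluated by ROC/AUC and stratified cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    e1071,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
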