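Package: gecscreen
Title: Ectopic Expression Biomarker Screening and Gene Expression Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A survival-based screening pipeline for ectopically activated
    tissue-specific genes in tumours. Identifies genes with predominant
    expression in target normal tissues (testis, placenta, embryonic stem
    cells) by a Z-score outlier rule, calls per-sample ON/OFF activation in
    tumour cohorts against mean + 2 SD thresholds fitted on non-tumour
    samples, scans expression thresholds over a percentile grid for stable,
    cross-validated associations with disease-free survival (logrank,
    Benjamini-Hochberg FDR, hazard-ratio and stability gates), propagates
    selected thresholds across cohorts as percentile ranks, and combines
    validated biomarkers into a gene-count classifier (GEC) evaluated by
    Kaplan-Meier, Cox and subtype-stratified analyses. Includes a synthetic
    cohort generator with planted tissue-predominant genes, controlled
    ectopic-activation frequencies and proportional-hazards survival
    structure, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
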