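Package: mirdose
Title: Integrative Copy-Number and Expression Analysis of MicroRNA Dosage
    Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying microRNAs whose expression is driven by
    DNA copy-number variation, and for tracing their downstream effects on
    target genes in patient cohorts. Implements copy-number state
    classification of SNP-array profiles with a recursive t-based
    segmenter, relative quantification of qPCR data by the 2^-ddCt method
    with mean +/- 3 SD deregulation calling against normal controls,
    per-miRNA association testing of expression against locus copy-number
    status, an empirical-Bayes moderated-t differential-expression screen
    with coherent (anti-correlated) target nomination, patient-level
    prevalence and mechanism-attribution analysis, and a synthetic
    multi-omics data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
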