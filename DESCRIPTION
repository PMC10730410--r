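Package: regeqtl
Title: Regulatory eQTL Case-Control Association and Gene-Level Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a brain-regulatory eQTL test set by intersecting
    significant eQTL catalogs with chromatin-accessibility peaks and Hi-C
    loop anchors, runs quality-controlled additive logistic case/control
    association with LD clumping and FDR index-variant selection,
    replicates hits against aggregate allele-frequency controls, scores
    genes by a log-Bayes-factor integration of eQTL and association
    evidence, and runs permutation-based differential-expression and
    EHR carrier contrasts. Ships a synthetic-data generator with planted,
    recoverable effects so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
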