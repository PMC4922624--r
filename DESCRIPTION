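Package: cnvpop
Title: Population-Level Copy Number Variation Analysis from SNP-Array Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-calling analysis of copy number variation (CNV)
    in diploid populations genotyped on SNP arrays. Reads per-sample CNV
    calls in the PennCNV text format, applies call-level quality filters,
    compiles calls into population CNV regions (CNVRs) with recurrence
    (density) trimming and gain/loss typing, tests CNVR overlap with
    annotation tracks (genes, QTLs, known CNVRs) by permutation against
    size- and chromosome-matched random regions, scans copy-number segments
    for association with a quantitative phenotype with false discovery rate
    control, and classifies qPCR Delta-Delta-Ct measurements into copy
    number states for validation of array-derived calls. A seeded synthetic
    data generator emulates SNP-array CNV calling in a diploid population
    so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
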