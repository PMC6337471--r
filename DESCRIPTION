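Package: refstab
Title: Reference-Gene Stability Evaluation and Normalization for qRT-PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for
    quantitative reverse-transcription PCR and normalizes target-gene
    expression against multi-gene normalization factors. Implements the
    comparative delta-Ct mean standard deviation, BestKeeper descriptive
    statistics and index correlation, the geNorm M-value with iterative
    exclusion and the V(n/n+1) pairwise-variation rule, a NormFinder-style
    inter/intra-group stability value, cross-entropy Monte-Carlo rank
    aggregation under the Spearman footrule, and GrayNorm-style exhaustive
    scoring of reference-gene combinations against a control condition.
    Includes amplification-efficiency estimation from dilution series,
    efficiency-corrected relative quantification, and a synthetic Ct-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
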