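Package: normsense
Title: Normalization-Sensitivity Analysis for qPCR Relative Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a qPCR conclusion about a treatment
    effect survives a change of reference gene. Implements
    efficiency-corrected (Pfaffl) relative quantification with
    standard-curve efficiency estimation and technical-replicate quality
    control, exact and approximate Wilcoxon rank-sum inference with
    Hodges-Lehmann location-shift estimates and confidence intervals,
    reference-gene stability scoring from expression compendia (including
    the expected-maximal-fold-change bound 2^(1.96*SD)), a two-group
    empirical-Bayes moderated-t differential expression stage with
    Benjamini-Hochberg adjustment, a curated literature-evidence table with
    tally operations, and seeded generators for Cq-level qPCR data,
    expression compendia and two-group matrices so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), limma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
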