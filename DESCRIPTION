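Package: giscan
Title: Copy-Number Instability Scoring of Shallow Whole-Genome cfDNA Sequencing
Version: 0.1.0
Authors@R:
    person("giscan", "maintainers", email = "giscan@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for shallow whole-genome sequencing of plasma
    cell-free DNA. Computes per-bin and gene-body read depth, removes GC bias
    with LOESS regression, builds a healthy-control reference model, derives
    depth Z-scores and threshold copy-number calls, summarises chromosomal
    instability as a genome-wide instability (Gi) score, and integrates calls
    with clinical outcomes (Kaplan-Meier, log-rank, CA125 subgroup analysis).
    Includes a synthetic cohort generator emulating GC-biased coverage, planted
    copy-number events diluted by tumor fraction, and outcome data, so the
    whole pipeline is testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    survival,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Biostrings
Config/testthat/edition: 3
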