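Package: ash36
Title: Integrative ChIP-Seq/RNA-Seq Analysis of H3K36 Methylation and
    Polycomb-Opposed Gene Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable pipeline for studying how Ash1l-dependent H3K36
    methylation counteracts Polycomb silencing during retinoic-acid (RA)
    induced differentiation of embryonic stem cells.  Provides
    retinoic-acid response classification of genes from FPKM tables
    (modified log2 fold changes), ChIP-Seq peak-to-gene association under
    TSS-window and upstream-plus-gene-body rules, chromatin-signature
    (bivalent/K4me3/K27me3) enrichment testing by chi-square against a
    background gene universe, region RPKM quantification with
    75th-percentile normalization, DRB-response fold-change grouping with
    RAR under-representation testing, metagene and anchor-centered
    coverage profiles, ChIP-qPCR percent-input summaries, phenotype
    penetrance tabulation, and a seeded synthetic-data generator that
    emulates the statistical structure of such experiments for testing
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
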