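Package: apoenet
Title: Rank-Based Transcriptional Signatures, Network Diffusion and
    APOE-SNP Epistasis Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomic-genomic analysis toolkit for
    two-group molecular studies. Implements a rank-based per-sample
    signature classifier with a weighted enrichment-score distance and
    genetic-algorithm parameter tuning; expansion of the resulting
    biomarker over a protein-interaction network by node-score-weighted
    random walk with restart and automatic edge-score thresholding;
    hypergeometric over-representation analysis of the expanded gene
    list; and a two-cohort SNP-by-APOE interaction scan on disease
    age-at-onset with sample-size-weighted Z meta-analysis, genomic
    control and FDR. A synthetic-data module generates expression,
    network, gene-set and genotype-phenotype fixtures with planted
    signal so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
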