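#!/usr/bin/env Rscript
# Generate every synthetic input for the analysis: a two-group cortex-like
# expression dataset with 50 planted discriminative probes (43 vs 34
# subjects), a scale-free protein-interaction network containing a planted
# 50-gene module that carries 80% of the informative genes, gene-set
# collections with one set drawn from that module, and two genotype cohorts
# (600 samples, 2000 shared SNPs) with five planted APOE-by-SNP interaction
# effects of +0.8 years per dosage unit on age-at-onset.

library(apoenet)

outdir <- "results/run"
run_pipeline(list(seed = 1L), outdir, stages = "simulate")

ds <- read_expression(file.path(outdir, "expression"))
net <- read_sif(file.path(outdir, "network.sif"))
cat("expression:", length(ds$probe_ids), "probes x", length(ds$sample_ids),
    "samples\n")
cat("network:", igraph::vcount(net), "genes,", igraph::ecount(net),
    "interactions; planted module:",
    length(readLines(file.path(outdir, "module_genes.txt"))), "genes\n")
cat("cohorts written under", outdir, "\n")
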