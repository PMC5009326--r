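#!/usr/bin/env Rscript
# Over-representation analysis of the expanded subnetwork gene list against
# the simulated gene-set collection, with the full network gene list as
# background and an FDR threshold of 0.001 — plus the simple fold-change /
# p-value differential-expression screen on the expression data for context.

library(apoenet)

outdir <- "results/run"
net <- read_sif(file.path(outdir, "network.sif"))
coll <- read_gmt(file.path(outdir, "gene_sets.gmt"),
                 universe = igraph::V(net)$name)
genes <- readLines("results/subnetwork_genes.txt")

res <- ora(genes, coll, fdr_threshold = 0.001)
n_sig <- sum(res$significant)
cat("gene sets tested:", nrow(res), "; significant at FDR 0.001:", n_sig, "\n")
cat("top set:", res$set[1], sprintf("(k=%d/K=%d, p=%.3g, q=%.3g)\n",
                                    res$k[1], res$K[1], res$p[1], res$q[1]))
write_results(res, "results/enrichment.tsv")

# targeted DE screen (1.5-fold change at p < 0.02, no multiplicity correction)
ds <- read_expression(file.path(outdir, "expression"))
g <- ds$group_labels
lv <- sort(unique(g))
de <- de_filter(ds$abundance[, g == lv[2]], ds$abundance[, g == lv[1]],
                fc_threshold = 1.5, p_threshold = 0.02, log2_input = TRUE)
cat("DE screen:", sum(de$pass), "of", nrow(de),
    "probes pass 1.5-fold change at p < 0.02\n")
write_results(de[de$pass, ], "results/de_filter_hits.tsv")
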