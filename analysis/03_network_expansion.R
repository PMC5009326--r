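#!/usr/bin/env Rscript
# Expand the transcriptional biomarker over the interaction network: biomarker
# genes get node scores -log2(filter p), a restart-0.5 random walk diffuses
# those scores, edges are ranked by log2 weighted-vs-baseline flux, the
# sorted-score curve is thresholded at its step (or top decile when no step
# stands out), and the above-threshold subnetwork is extracted. Recovery is
# quantified as Jaccard overlap with the planted module.

library(apoenet)

outdir <- "results/run"
net <- read_sif(file.path(outdir, "network.sif"))
bm <- utils::read.delim("results/biomarker.tsv")
gene_p <- tapply(bm$p, bm$gene, min)

scores <- assign_node_scores(net, stats::setNames(as.numeric(gene_p),
                                                  names(gene_p)))
et <- edge_scores(net, scores, restart = 0.5)
thr <- detect_threshold(et$score)
cat(sprintf("edge-score threshold %.3f (%s rule)\n", thr,
            attr(thr, "method")))

sub <- extract_subnetwork(net, et, thr)
cat("subnetwork:", length(sub$genes), "genes,", nrow(sub$edges),
    "interactions in", length(sub$components), "component(s)\n")

module <- readLines(file.path(outdir, "module_genes.txt"))
jac <- length(intersect(sub$genes, module)) /
  length(union(sub$genes, module))
cat(sprintf("Jaccard overlap with the planted module: %.3f\n", jac))

write_results(et, "results/edge_scores.tsv")
writeLines(sub$genes, "results/subnetwork_genes.txt")
write_sif(sub$graph, "results/subnetwork.sif")
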