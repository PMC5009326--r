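#!/usr/bin/env Rscript
# Rank-based signature classification of the two sample groups: Wilcoxon
# probe filtering, per-sample top/bottom signatures, enrichment-score
# distances, ten-fold cross-validation, a label-permutation significance
# test, and extraction of the biomarker (probes used by at least one
# signature). A small GA search over (n1, n2, alpha) illustrates automatic
# parameter selection.

library(apoenet)

outdir <- "results/run"
ds <- read_expression(file.path(outdir, "expression"))

params <- classifier_params(n1 = 10, n2 = 10, alpha_filter = 0.01)
cv <- cross_validate(ds, params, n_folds = 10, seed = 11)
cat(sprintf("10-fold CV: accuracy %.3f (sd %.3f), precision %.3f, recall %.3f\n",
            cv$mean_accuracy, cv$sd_accuracy, cv$mean_precision,
            cv$mean_recall))

pt <- permutation_test(ds, params, n_perm = 999, seed = 12)
cat(sprintf("permutation test: observed accuracy %.3f, p = %.4f (999 label permutations)\n",
            pt$observed, pt$p))

ga <- ga_optimize(ds,
                  space = list(n1 = c(5, 10, 15, 20), n2 = c(5, 10, 15, 20),
                               alpha_filter = c(0.005, 0.01, 0.05)),
                  control = ga_control(pop_size = 12, n_generations = 6),
                  n_folds = 5, seed = 13)
cat(sprintf("GA-selected parameters: n1=%d n2=%d alpha=%.3f (fitness %.3f)\n",
            ga$best_params$n1, ga$best_params$n2,
            ga$best_params$alpha_filter, ga$best_fitness))

flt <- wilcoxon_filter(ds, params$alpha_filter)
dm <- distance_matrix(ds, flt$retained, params$n1, params$n2)
bm <- extract_biomarker(dm$signatures, ds$probe_to_gene, flt$pvalues)
cat("biomarker:", length(bm$probe_ids), "probes /",
    length(bm$gene_symbols), "genes\n")

write_results(data.frame(probe = bm$probe_ids, gene = unname(bm$gene_of),
                         p = unname(bm$filter_pvalues)),
              "results/biomarker.tsv")
write_results(cv$per_fold, "results/cv_folds.tsv")
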