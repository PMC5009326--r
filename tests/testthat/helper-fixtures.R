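# Small fixtures built in code; all deterministic via explicit seeds.

# Hand-built expression dataset from a matrix (probes x samples).
manual_dataset <- function(mat, groups, genes = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("P%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  if (is.null(genes)) genes <- stats::setNames(paste0("G_", rownames(mat)),
                                               rownames(mat))
  expression_dataset(mat, groups, genes)
}

# Quick separable two-group dataset.
sim_ds <- function(seed = 1, n_probes = 300L, groups = c(15L, 15L),
                   n_informative = 30L, effect = 2, modality = "microarray") {
  simulate_expression(expr_sim_config(
    n_probes = n_probes, n_samples_per_group = groups,
    n_informative = n_informative, effect_size = effect, modality = modality,
    seed = seed))
}

# Brute-force running-sum enrichment score (independent oracle).
brute_es <- function(set, ranking, q = 1) {
  N <- length(ranking)
  hit <- ranking %in% set
  w <- abs((N + 1) / 2 - seq_len(N))^q
  hw <- w * hit
  denom <- sum(hw)
  if (denom <= 0) { hw <- as.numeric(hit); denom <- sum(hit) }
  p_hit <- cumsum(hw) / denom
  nm <- N - sum(hit)
  p_miss <- if (nm > 0) cumsum(!hit) / nm else rep(0, N)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

# Small star/ring igraphs with names.
named_ring <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
named_star <- function(n) {
  g <- igraph::make_star(n, mode = "undirected")
  igraph::V(g)$name <- c("hub", sprintf("leaf%02d", seq_len(n - 1L)))
  g
}

# Minimal genotype cohort from explicit pieces.
manual_cohort <- function(dosage, chrom = NULL, pos = NULL, aao = NULL,
                          apoe = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("I%03d", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("s%03d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(aao)) aao <- rep(75, n)
  if (is.null(apoe)) apoe <- rep(1L, n)
  genotype_cohort(dosage,
                  data.frame(snp = colnames(dosage), chrom = chrom, pos = pos,
                             A1 = "A", A2 = "G", stringsAsFactors = FALSE),
                  data.frame(sample_id = rownames(dosage), aao = aao,
                             apoe4 = apoe, stringsAsFactors = FALSE))
}
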