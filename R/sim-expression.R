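#' Configuration for the expression simulator
#'
#' Describes a two-group probe-level expression experiment with a planted set
#' of discriminative probes. Defaults mirror a post-mortem cortex case/case
#' design stratified by APOE genotype: 43 vs 34 subjects, microarray-like
#' log-scale abundances.
#'
#' @param n_probes total number of probes on the array.
#' @param n_samples_per_group integer pair; sizes of the two phenotype groups.
#' @param n_informative number of probes carrying a planted between-group
#'   shift; must not exceed `n_probes`.
#' @param effect_size standardized mean shift (in units of `noise_sd`) planted
#'   on informative probes. Direction is randomized per probe so that both
#'   over- and under-expressed probes occur.
#' @param noise_sd within-group standard deviation of log-scale abundance.
#' @param modality `"microarray"` (Gaussian log-scale abundances) or
#'   `"rnaseq"` (log2 of negative-binomial counts).
#' @param group_labels character pair naming the two groups.
#' @param seed integer seed; identical configurations reproduce identical
#'   datasets.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_probes = 1000L,
                            n_samples_per_group = c(43L, 34L),
                            n_informative = 50L,
                            effect_size = 2,
                            noise_sd = 1,
                            modality = c("microarray", "rnaseq"),
                            group_labels = c("APOE33", "APOE44"),
                            seed = 1L) {
  modality <- match.arg(modality)
  n_probes <- as.integer(n_probes)
  n_samples_per_group <- as.integer(n_samples_per_group)
  n_informative <- as.integer(n_informative)
  if (length(n_samples_per_group) != 2L || any(n_samples_per_group < 2L))
    stop("n_samples_per_group must be two counts, each >= 2", call. = FALSE)
  if (n_probes < 1L || n_informative < 0L || n_informative > n_probes)
    stop("need 0 <= n_informative <= n_probes and n_probes >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (length(group_labels) != 2L || anyDuplicated(group_labels))
    stop("group_labels must be two distinct labels", call. = FALSE)
  structure(list(n_probes = n_probes,
                 n_samples_per_group = n_samples_per_group,
                 n_informative = n_informative,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 modality = modality,
                 group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Construct an expression dataset
#'
#' The classifier's substrate: a probe-by-sample abundance matrix with two
#' group labels and a many-to-one probe-to-gene map.
#'
#' @param abundance numeric matrix, probes in rows, samples in columns.
#' @param group_labels character/factor of length `ncol(abundance)` with
#'   exactly two distinct values.
#' @param probe_to_gene named character vector mapping every probe id to a
#'   gene symbol.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(abundance, group_labels, probe_to_gene) {
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance must have probe row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(abundance)) || anyDuplicated(colnames(abundance)))
    stop("duplicate probe or sample ids", call. = FALSE)
  if (!all(is.finite(abundance)))
    stop("abundance matrix must be finite", call. = FALSE)
  group_labels <- as.character(group_labels)
  if (length(group_labels) != ncol(abundance))
    stop("one group label per sample required", call. = FALSE)
  if (length(unique(group_labels)) != 2L)
    stop("exactly two distinct group labels required", call. = FALSE)
  missing_map <- setdiff(rownames(abundance), names(probe_to_gene))
  if (length(missing_map))
    stop("probe_to_gene lacks entries for ", length(missing_map), " probes",
         call. = FALSE)
  structure(list(abundance = abundance,
                 probe_ids = rownames(abundance),
                 sample_ids = colnames(abundance),
                 group_labels = stats::setNames(group_labels,
                                                colnames(abundance)),
                 probe_to_gene = probe_to_gene[rownames(abundance)]),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$group_labels)
  cat("expression_dataset:", length(x$probe_ids), "probes x",
      length(x$sample_ids), "samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Simulate a two-group expression dataset with planted signal
#'
#' Generates log-scale abundances in which `n_informative` probes carry a
#' between-group mean difference of `effect_size * noise_sd` (random sign per
#' probe); all other probes are exchangeable between groups. In `"rnaseq"`
#' mode the same mean structure drives negative-binomial counts which are then
#' log2(count+1)-transformed. A small fraction of probes share a gene symbol,
#' so the probe-to-gene map is many-to-one as on real platforms.
#'
#' @param cfg an [expr_sim_config()].
#' @return An [expression_dataset()] with attributes `informative_probes`,
#'   `informative_genes` and `planted_shift` recording the ground truth.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  n <- sum(cfg$n_samples_per_group)
  withr_seed(cfg$seed, {
    probe_ids <- sprintf("P%05d", seq_len(cfg$n_probes))
    sample_ids <- sprintf("S%03d", seq_len(n))
    groups <- rep(cfg$group_labels, cfg$n_samples_per_group)

    # many-to-one probe->gene map: ~5% of probes are duplicate measurements
    gene_of <- sprintf("GENE%05d", seq_len(cfg$n_probes))
    n_dup <- floor(0.05 * cfg$n_probes)
    if (n_dup > 0 && cfg$n_probes > 2L * n_dup) {
      dup_from <- sample(seq_len(cfg$n_probes), n_dup)
      dup_to <- sample(setdiff(seq_len(cfg$n_probes), dup_from), n_dup)
      gene_of[dup_to] <- gene_of[dup_from]
    }
    names(gene_of) <- probe_ids

    informative <- sort(sample(seq_len(cfg$n_probes), cfg$n_informative))
    # informative probes get unique genes so planted network modules are clean
    gene_of[informative] <- sprintf("GENE%05d", informative)
    shift_sign <- sample(c(-1, 1), cfg$n_informative, replace = TRUE)
    delta <- numeric(cfg$n_probes)
    delta[informative] <- shift_sign * cfg$effect_size * cfg$noise_sd

    baseline <- stats::rnorm(cfg$n_probes, mean = 8, sd = 2)
    mu <- matrix(baseline, cfg$n_probes, n) +
      outer(delta, as.numeric(groups == cfg$group_labels[2L]))

    if (cfg$modality == "microarray") {
      mat <- mu + matrix(stats::rnorm(cfg$n_probes * n, sd = cfg$noise_sd),
                         cfg$n_probes, n)
    } else {
      counts <- matrix(stats::rnbinom(cfg$n_probes * n, mu = pmax(2^mu, 1e-8),
                                      size = 10),
                       cfg$n_probes, n)
      mat <- log2(counts + 1)
    }
    dimnames(mat) <- list(probe_ids, sample_ids)

    ds <- expression_dataset(mat, groups, gene_of)
    attr(ds, "informative_probes") <- probe_ids[informative]
    attr(ds, "informative_genes") <- unname(gene_of[informative])
    attr(ds, "planted_shift") <- stats::setNames(delta[informative],
                                                 probe_ids[informative])
    ds
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generator determinism flows through this.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
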