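#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the package defaults filled
#' in. `run_pipeline()` rejects configurations containing keys not present
#' here, so typos fail loudly rather than being silently ignored.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    expression = list(n_probes = 1000L, n_samples_per_group = c(43L, 34L),
                      n_informative = 50L, effect_size = 2, noise_sd = 1,
                      modality = "microarray"),
    network = list(n_genes = 500L, attachment_parameter = 2L,
                   planted_module_size = 50L, planted_overlap = 0.8,
                   module_mean_degree = 4),
    gene_sets = list(n_sets = 50L, set_size_range = c(10L, 40L),
                     true_frac = 1),
    cohorts = list(n_samples = 600L, n_snps = 2000L,
                   maf_range = c(0.05, 0.5), n_interacting = 5L,
                   beta_interaction = 0.8, structure_strength = 0.05,
                   aao_mean = 75, aao_sd = 5, shared_snps = 2000L),
    classifier = list(n1 = 10L, n2 = 10L, alpha_filter = 0.01,
                      weight_exponent = 1, n_folds = 10L, optimize = FALSE,
                      ga_pop = 10L, ga_generations = 5L,
                      space_n1 = c(5L, 10L, 15L), space_n2 = c(5L, 10L, 15L),
                      space_alpha = c(0.005, 0.01, 0.05)),
    walk = list(restart = 0.5, threshold = "auto"),
    enrich = list(fdr_threshold = 0.001),
    epistasis = list(snp_call = 0.95, maf = 0.05, sample_call = 0.95,
                     n_axes = 3L, genomic_control = TRUE, q_threshold = 0.05)
  )
}

check_config_keys <- function(config, defaults, path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(config))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      check_config_keys(as.list(config[[k]]), defaults[[k]],
                        paste0(path, k, "$"))
  invisible(TRUE)
}

merge_config <- function(config, defaults) {
  for (k in names(defaults)) {
    if (!k %in% names(config)) config[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      config[[k]] <- merge_config(as.list(config[[k]]), defaults[[k]])
  }
  config
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: data simulation, classifier cross-validation (or GA
#' optimization), biomarker extraction, network random walk with edge-score
#' thresholding, over-representation analysis, and the two-cohort epistasis
#' scan with meta-analysis. Each stage writes its outputs as TSV under
#' `outdir` and later stages consume those files, so any stage can be re-run
#' from disk. A JSON run manifest (configuration, package version, per-file
#' checksums, timestamps) is written at the end; if a stage fails, the
#' manifest records the failed stage before the error propagates.
#'
#' @param config nested list as from [default_config()]; partial
#'   configurations are completed with defaults, unknown keys are an error.
#' @param outdir output directory, created if needed.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "classify", "biomarker", "walk", "enrich", "epistasis")`;
#'   earlier stages' outputs must already exist in `outdir` when skipped.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir,
                         stages = c("simulate", "classify", "biomarker",
                                    "walk", "enrich", "epistasis")) {
  defaults <- default_config()
  check_config_keys(config, defaults)
  config <- merge_config(config, defaults)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("apoenet")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages_run = character(), failed_stage = NULL)
  current <- NULL
  on.exit({
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest$failed_stage <- current
    files <- list.files(outdir, pattern = "\\.(tsv|txt|gmt|sif)$",
                        full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  })
  pth <- function(...) file.path(outdir, ...)

  if ("simulate" %in% stages) {
    current <- "simulate"
    e <- config$expression
    ds <- simulate_expression(expr_sim_config(
      n_probes = e$n_probes, n_samples_per_group = e$n_samples_per_group,
      n_informative = e$n_informative, effect_size = e$effect_size,
      noise_sd = e$noise_sd, modality = e$modality, seed = seed))
    write_expression(ds, pth("expression"))
    writeLines(attr(ds, "informative_genes"), pth("informative_genes.txt"))

    nw <- config$network
    net <- simulate_network(net_sim_config(
      n_genes = nw$n_genes, attachment_parameter = nw$attachment_parameter,
      planted_module_size = nw$planted_module_size,
      planted_overlap = nw$planted_overlap,
      module_mean_degree = nw$module_mean_degree, seed = seed + 1L),
      informative_genes = attr(ds, "informative_genes"),
      background_genes = unique(unname(ds$probe_to_gene)))
    write_sif(net, pth("network.sif"))
    writeLines(attr(net, "module_genes"), pth("module_genes.txt"))

    gs <- config$gene_sets
    coll <- simulate_gene_sets(net, attr(net, "module_genes"),
                               n_sets = gs$n_sets,
                               set_size_range = gs$set_size_range,
                               true_frac = gs$true_frac, seed = seed + 2L)
    write_gmt(coll, pth("gene_sets.gmt"))

    co <- config$cohorts
    mk <- function(s) geno_sim_config(
      n_samples = co$n_samples, n_snps = co$n_snps,
      maf_range = co$maf_range, n_interacting = co$n_interacting,
      beta_interaction = co$beta_interaction,
      structure_strength = co$structure_strength, aao_mean = co$aao_mean,
      aao_sd = co$aao_sd, seed = s)
    cohorts <- simulate_cohorts(mk(seed + 3L), mk(seed + 4L),
                                shared_snps = co$shared_snps)
    write_cohort(cohorts[[1L]], pth("cohort1"))
    write_cohort(cohorts[[2L]], pth("cohort2"))
    writeLines(attr(cohorts, "planted_snps"), pth("planted_snps.txt"))
    manifest$stages_run <- c(manifest$stages_run, "simulate")
  }

  cl <- config$classifier
  if ("classify" %in% stages) {
    current <- "classify"
    ds <- read_expression(pth("expression"))
    if (isTRUE(cl$optimize)) {
      opt <- ga_optimize(ds, space = list(n1 = cl$space_n1, n2 = cl$space_n2,
                                          alpha_filter = cl$space_alpha),
                         control = ga_control(pop_size = cl$ga_pop,
                                              n_generations = cl$ga_generations),
                         n_folds = cl$n_folds,
                         weight_exponent = cl$weight_exponent,
                         seed = seed + 10L)
      params <- opt$best_params
      cv <- opt$cv
    } else {
      params <- classifier_params(cl$n1, cl$n2, cl$alpha_filter,
                                  cl$weight_exponent)
      cv <- cross_validate(ds, params, cl$n_folds, seed = seed + 10L)
    }
    write_results(data.frame(n1 = params$n1, n2 = params$n2,
                             alpha_filter = params$alpha_filter,
                             weight_exponent = params$weight_exponent,
                             cv_accuracy = cv$mean_accuracy,
                             cv_precision = cv$mean_precision,
                             cv_recall = cv$mean_recall),
                  pth("classifier.tsv"))
    manifest$stages_run <- c(manifest$stages_run, "classify")
  }

  if ("biomarker" %in% stages) {
    current <- "biomarker"
    ds <- read_expression(pth("expression"))
    pr <- utils::read.delim(pth("classifier.tsv"))
    flt <- wilcoxon_filter(ds, pr$alpha_filter)
    dm_rank <- rank_all_samples(ds, flt$retained)
    sigs <- lapply(dm_rank, build_signature, n1 = pr$n1, n2 = pr$n2)
    bm <- extract_biomarker(sigs, ds$probe_to_gene, flt$pvalues)
    gp <- biomarker_gene_pvalues(bm)
    write_results(data.frame(gene = names(gp), p = unname(gp)),
                  pth("biomarker_genes.tsv"))
    write_results(data.frame(probe = bm$probe_ids,
                             gene = unname(bm$gene_of),
                             p = unname(bm$filter_pvalues)),
                  pth("biomarker_probes.tsv"))
    manifest$stages_run <- c(manifest$stages_run, "biomarker")
  }

  if ("walk" %in% stages) {
    current <- "walk"
    net <- read_sif(pth("network.sif"))
    bg <- utils::read.delim(pth("biomarker_genes.tsv"))
    scores <- suppressWarnings(
      assign_node_scores(net, stats::setNames(bg$p, bg$gene)))
    et <- edge_scores(net, scores, restart = config$walk$restart)
    thr <- if (identical(config$walk$threshold, "auto"))
      detect_threshold(et$score) else as.numeric(config$walk$threshold)
    sub <- extract_subnetwork(net, et, thr)
    write_results(et, pth("edge_scores.tsv"))
    write_sif(sub$graph, pth("subnetwork.sif"))
    writeLines(sub$genes, pth("subnetwork_genes.txt"))
    manifest$stages_run <- c(manifest$stages_run, "walk")
  }

  if ("enrich" %in% stages) {
    current <- "enrich"
    net <- read_sif(pth("network.sif"))
    coll <- read_gmt(pth("gene_sets.gmt"),
                     universe = igraph::V(net)$name)
    genes <- readLines(pth("subnetwork_genes.txt"))
    res <- suppressWarnings(
      ora(genes, coll, fdr_threshold = config$enrich$fdr_threshold))
    write_results(res, pth("enrichment.tsv"))
    manifest$stages_run <- c(manifest$stages_run, "enrich")
  }

  if ("epistasis" %in% stages) {
    current <- "epistasis"
    ep <- config$epistasis
    run_one <- function(tag) {
      co <- read_cohort(pth(tag))
      q <- qc(co, snp_call = ep$snp_call, maf = ep$maf,
              sample_call = ep$sample_call)
      mds <- mds_covariates(q$cohort, n_axes = ep$n_axes)
      interaction_scan(q$cohort, covariates = mds)
    }
    r1 <- run_one("cohort1"); r2 <- run_one("cohort2")
    meta <- meta_analyze(r1, r2, genomic_control = ep$genomic_control)
    meta <- direction_filter(meta)
    meta$significant <- meta$q < ep$q_threshold
    write_results(r1, pth("epistasis_cohort1.tsv"))
    write_results(r2, pth("epistasis_cohort2.tsv"))
    write_results(meta, pth("epistasis_meta.tsv"))
    manifest$stages_run <- c(manifest$stages_run, "epistasis")
  }

  current <- NULL
  invisible(manifest)
}
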