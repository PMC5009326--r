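#' Configuration for a genotype-phenotype cohort simulator
#'
#' Describes one case cohort with additive SNP dosages, APOE epsilon-4 allele
#' counts, and age-at-onset (AAO) generated under a linear model with a
#' planted APOE-by-SNP interaction:
#' `AAO = aao_mean + b_apoe*APOE4 + b_snp*dosage +
#'  beta_interaction*(APOE4*dosage) + structure offset + N(0, aao_sd)`.
#'
#' @param n_samples cohort size.
#' @param n_snps number of SNPs genotyped.
#' @param maf_range interval in `(0, 0.5]` from which minor allele frequencies
#'   are drawn uniformly.
#' @param n_interacting number of SNPs with a planted interaction effect.
#' @param beta_interaction interaction effect in years per
#'   (APOE4 count x dosage) unit.
#' @param b_apoe main APOE4 effect on AAO, years per allele. Negative by
#'   default: epsilon-4 lowers the onset age.
#' @param b_snp main SNP effect on AAO, years per dosage unit.
#' @param aao_mean,aao_sd mean and residual SD of age-at-onset, years.
#' @param structure_strength scale of allele-frequency divergence between the
#'   two latent subpopulations; also drives a subpopulation AAO offset of
#'   `2 * structure_strength` years, so MDS adjustment is consequential.
#' @param missing_rate per-genotype missingness rate.
#' @param apoe_probs probabilities of APOE4 counts 0/1/2.
#' @param seed integer seed.
#' @return An object of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_samples = 600L,
                            n_snps = 2000L,
                            maf_range = c(0.05, 0.5),
                            n_interacting = 5L,
                            beta_interaction = 0.8,
                            b_apoe = -2.5,
                            b_snp = 0,
                            aao_mean = 75,
                            aao_sd = 5,
                            structure_strength = 0,
                            missing_rate = 0.01,
                            apoe_probs = c(0.30, 0.46, 0.24),
                            seed = 1L) {
  n_samples <- as.integer(n_samples); n_snps <- as.integer(n_snps)
  n_interacting <- as.integer(n_interacting)
  if (n_interacting > n_snps)
    stop("n_interacting must not exceed n_snps", call. = FALSE)
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L])
    stop("maf_range must be an interval in (0, 0.5]", call. = FALSE)
  if (aao_sd <= 0) stop("aao_sd must be positive", call. = FALSE)
  if (structure_strength < 0) stop("structure_strength must be >= 0", call. = FALSE)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 maf_range = maf_range, n_interacting = n_interacting,
                 beta_interaction = beta_interaction, b_apoe = b_apoe,
                 b_snp = b_snp, aao_mean = aao_mean, aao_sd = aao_sd,
                 structure_strength = structure_strength,
                 missing_rate = missing_rate, apoe_probs = apoe_probs,
                 seed = as.integer(seed)),
            class = "geno_sim_config")
}

#' Construct a genotype cohort
#'
#' @param dosage sample-by-SNP matrix of additive dosages in `{0,1,2}` with
#'   `NA` for missing genotypes; row names are sample ids, column names SNP
#'   ids.
#' @param snp_meta data frame with columns `snp`, `chrom`, `pos` (1-based),
#'   `A1`, `A2`.
#' @param pheno data frame with columns `sample_id`, `aao` (years) and
#'   `apoe4` (epsilon-4 allele count in `{0,1,2}`), plus optional covariates.
#' @return An object of class `genotype_cohort`.
#' @export
genotype_cohort <- function(dosage, snp_meta, pheno) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage needs sample row names and SNP column names", call. = FALSE)
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("duplicate sample or SNP ids", call. = FALSE)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  req <- c("snp", "chrom", "pos", "A1", "A2")
  if (!all(req %in% names(snp_meta)))
    stop("snp_meta must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!setequal(snp_meta$snp, colnames(dosage)))
    stop("snp_meta does not match dosage columns", call. = FALSE)
  if (any(snp_meta$pos < 1)) stop("positions must be positive", call. = FALSE)
  if (!all(c("sample_id", "aao", "apoe4") %in% names(pheno)))
    stop("pheno must have sample_id, aao, apoe4", call. = FALSE)
  if (!setequal(pheno$sample_id, rownames(dosage)))
    stop("pheno does not match dosage rows", call. = FALSE)
  snp_meta <- snp_meta[match(colnames(dosage), snp_meta$snp), , drop = FALSE]
  pheno <- pheno[match(rownames(dosage), pheno$sample_id), , drop = FALSE]
  rownames(snp_meta) <- rownames(pheno) <- NULL
  structure(list(dosage = dosage, snp_meta = snp_meta, pheno = pheno),
            class = "genotype_cohort")
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat("genotype_cohort:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs; AAO mean", round(mean(x$pheno$aao), 1), "y\n")
  invisible(x)
}

#' Simulate two genotype-phenotype cohorts sharing SNPs
#'
#' The first `shared_snps` SNPs (metadata and underlying allele frequencies)
#' are common to both cohorts; planted interacting SNPs are drawn from the
#' shared set and carry interaction effects of the same sign in both cohorts,
#' so two-study meta-analysis has a recoverable signal. Each cohort contains
#' two latent subpopulations whose allele-frequency divergence and AAO offset
#' scale with `structure_strength`.
#'
#' @param cfg1,cfg2 [geno_sim_config()] objects for the two cohorts; their
#'   `beta_interaction` must share a sign.
#' @param shared_snps number of SNPs common to the two cohorts; must not
#'   exceed either `n_snps`.
#' @return List of two [genotype_cohort()] objects with attributes
#'   `planted_snps` and (per cohort) `subpop`.
#' @export
simulate_cohorts <- function(cfg1, cfg2, shared_snps = min(cfg1$n_snps,
                                                           cfg2$n_snps)) {
  stopifnot(inherits(cfg1, "geno_sim_config"),
            inherits(cfg2, "geno_sim_config"))
  if (shared_snps > min(cfg1$n_snps, cfg2$n_snps))
    stop("shared_snps exceeds a cohort's SNP count", call. = FALSE)
  if (sign(cfg1$beta_interaction) * sign(cfg2$beta_interaction) < 0)
    stop("planted interaction effects must share a sign across cohorts",
         call. = FALSE)
  n_int <- min(cfg1$n_interacting, cfg2$n_interacting, shared_snps)

  shared_meta <- withr_seed(cfg1$seed + 1000L, {
    make_snp_meta(shared_snps, prefix = "rs1")
  })
  shared_maf <- withr_seed(cfg1$seed + 2000L, {
    stats::runif(shared_snps, cfg1$maf_range[1L], cfg1$maf_range[2L])
  })
  planted <- if (n_int > 0) shared_meta$snp[seq_len(n_int)] else character()

  cohorts <- list(
    simulate_one_cohort(cfg1, shared_meta, shared_maf, planted, tag = "C1"),
    simulate_one_cohort(cfg2, shared_meta, shared_maf, planted, tag = "C2"))
  attr(cohorts, "planted_snps") <- planted
  cohorts
}

make_snp_meta <- function(n, prefix = "rs") {
  data.frame(snp = sprintf("%s%06d", prefix, seq_len(n)),
             chrom = as.character(sample(1:22, n, replace = TRUE)),
             pos = sample.int(2e8, n),
             A1 = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             A2 = rep(NA_character_, n), stringsAsFactors = FALSE) -> m
  m$A2 <- vapply(m$A1, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1L),
                 character(1))
  m
}

simulate_one_cohort <- function(cfg, shared_meta, shared_maf, planted, tag) {
  withr_seed(cfg$seed, {
    n_extra <- cfg$n_snps - nrow(shared_meta)
    meta <- shared_meta
    maf <- shared_maf
    if (n_extra > 0) {
      extra <- make_snp_meta(n_extra, prefix = paste0("rs", tag))
      meta <- rbind(meta, extra)
      maf <- c(maf, stats::runif(n_extra, cfg$maf_range[1L], cfg$maf_range[2L]))
    }
    n <- cfg$n_samples
    m <- nrow(meta)
    sample_ids <- sprintf("%s_%04d", tag, seq_len(n))

    subpop <- sample(1:2, n, replace = TRUE)
    div <- stats::rnorm(m, sd = cfg$structure_strength)
    p1 <- pmin(pmax(maf + div / 2, 0.01), 0.99)
    p2 <- pmin(pmax(maf - div / 2, 0.01), 0.99)
    pmat <- rbind(p1, p2)[subpop, , drop = FALSE]  # n x m
    dosage <- matrix(stats::rbinom(n * m, 2L, as.vector(pmat)), n, m)
    dimnames(dosage) <- list(sample_ids, meta$snp)

    apoe <- sample(0:2, n, replace = TRUE, prob = cfg$apoe_probs)
    aao <- cfg$aao_mean + cfg$b_apoe * apoe +
      2 * cfg$structure_strength * (subpop == 2L) +
      stats::rnorm(n, sd = cfg$aao_sd)
    for (s in planted) {
      d <- dosage[, s]
      aao <- aao + cfg$b_snp * d + cfg$beta_interaction * apoe * d
    }

    if (cfg$missing_rate > 0) {
      miss <- stats::runif(n * m) < cfg$missing_rate
      dosage[miss] <- NA_integer_
    }
    pheno <- data.frame(sample_id = sample_ids, aao = aao, apoe4 = apoe,
                        stringsAsFactors = FALSE)
    co <- genotype_cohort(dosage, meta, pheno)
    attr(co, "subpop") <- subpop
    attr(co, "planted_snps") <- planted
    co
  })
}
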