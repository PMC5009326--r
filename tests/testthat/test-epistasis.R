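test_that("QC removes low-MAF, low-call-rate and non-autosomal SNPs", {
  set.seed(44)
  n <- 100
  m_fill <- 20
  dos <- matrix(rbinom(n * (m_fill + 4), 2, 0.3), nrow = n)
  colnames(dos) <- c(sprintf("fill%02d", seq_len(m_fill)),
                     "ok", "rare", "holes", "chrx")
  rownames(dos) <- sprintf("I%03d", 1:n)
  dos[, "rare"] <- rep(c(0L, 1L), c(93, 7))  # MAF 0.035 < 0.05
  dos[1:7, "holes"] <- NA                    # call rate 0.93 < 0.95
  co <- manual_cohort(dos, chrom = c(rep("1", m_fill), "1", "2", "3", "X"))
  res <- qc(co)
  expect_true("ok" %in% colnames(res$cohort$dosage))
  expect_true("rare" %in% res$report$snps_low_maf)
  expect_true("holes" %in% res$report$snps_low_call)
  expect_true("chrx" %in% res$report$snps_non_autosome)
  expect_equal(unname(res$report$n_snps), c(24L, 21L))
  # sample call-rate rule: a sample missing most genotypes is excluded
  dos2 <- dos[, 1:20]
  dos2[1, 1:10] <- NA
  res2 <- qc(manual_cohort(dos2, chrom = rep("1", 20)))
  expect_true("I001" %in% res2$report$samples_removed)
})

test_that("MDS coordinates separate planted subpopulations and are stable", {
  cfg <- geno_sim_config(n_samples = 150, n_snps = 400,
                         structure_strength = 0.25, missing_rate = 0.01,
                         n_interacting = 0, seed = 21)
  hits <- vapply(1:10, function(s) {
    cfg$seed <- 20 + s
    co <- simulate_cohorts(cfg, cfg, shared_snps = 0)[[1]]
    mds <- mds_covariates(co)
    abs(stats::cor(mds$MDS1, attr(co, "subpop")))
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.9)

  # identical samples collapse to identical coordinates
  dos <- matrix(rep(c(0, 1, 2, 1, 0), 8), nrow = 4, byrow = TRUE,
                dimnames = list(sprintf("I%03d", 1:4), sprintf("s%03d", 1:10)))
  mds0 <- mds_covariates(manual_cohort(dos), n_axes = 2)
  expect_lt(max(abs(mds0$MDS1)), 1e-10)

  # sample order only permutes the rows
  co <- simulate_cohorts(geno_sim_config(n_samples = 40, n_snps = 100,
                                         seed = 3),
                         geno_sim_config(n_samples = 40, n_snps = 100,
                                         seed = 4), shared_snps = 0)[[1]]
  m1 <- mds_covariates(co)
  perm <- sample(nrow(co$dosage))
  co2 <- genotype_cohort(co$dosage[perm, ], co$snp_meta,
                         co$pheno[perm, ])
  m2 <- mds_covariates(co2)
  m2o <- m2[match(m1$sample_id, m2$sample_id), ]
  expect_equal(m1$MDS1, m2o$MDS1, tolerance = 1e-8)
})

test_that("interaction coefficients match a normal-equations oracle", {
  set.seed(55)
  n <- 12
  dos <- matrix(rbinom(n, 2, 0.4), ncol = 1,
                dimnames = list(sprintf("I%03d", 1:n), "snp1"))
  apoe <- rbinom(n, 2, 0.5)
  aao <- 70 + 1.5 * apoe - 0.5 * dos[, 1] + 0.9 * apoe * dos[, 1] + rnorm(n)
  co <- manual_cohort(dos, aao = aao, apoe = apoe)
  res <- interaction_scan(co, min_complete = 5)
  X <- cbind(1, apoe, dos[, 1], apoe * dos[, 1])
  beta <- solve(t(X) %*% X, t(X) %*% aao)
  resid <- aao - X %*% beta
  s2 <- sum(resid^2) / (n - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[4, 4])
  expect_equal(res$beta_int, beta[4], tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(beta[4] / se), n - 4), tolerance = 1e-10)
})

test_that("monomorphic SNPs are flagged rather than dropped", {
  set.seed(5)
  n <- 30
  dos <- cbind(poly = rbinom(n, 2, 0.5), mono = rep(1, n))
  rownames(dos) <- sprintf("I%03d", 1:n)
  co <- manual_cohort(dos, aao = rnorm(n, 75), apoe = rbinom(n, 2, 0.5))
  res <- interaction_scan(co, min_complete = 5)
  expect_equal(nrow(res), 2)
  expect_equal(res$note[res$snp == "mono"], "collinear")
  expect_true(is.na(res$p[res$snp == "mono"]))
  expect_false(is.na(res$p[res$snp == "poly"]))
})

test_that("meta-analysis closed forms hold", {
  r <- data.frame(snp = c("a", "b"), beta_int = c(1, -1), se = 1,
                  t = c(2, -2), p = c(0.04, 0.04), n_used = c(100, 100),
                  direction = c("+", "-"), note = "",
                  stringsAsFactors = FALSE)
  m_same <- meta_analyze(r, r, genomic_control = FALSE)
  z <- z_from_p(0.04, 1)
  expect_equal(m_same$z_meta[m_same$snp == "a"], sqrt(2) * z,
               tolerance = 1e-10)
  expect_equal(m_same$direction, c("++", "--"))
  r2 <- r; r2$beta_int <- -r$beta_int
  m_opp <- meta_analyze(r, r2, genomic_control = FALSE)
  expect_equal(m_opp$z_meta, c(0, 0), tolerance = 1e-12)
  expect_equal(m_opp$p_meta, c(1, 1), tolerance = 1e-12)
})

test_that("genomic inflation factor is near 1 on simulated null scans", {
  set.seed(61)
  n_snps <- 5000
  z_null <- rnorm(n_snps)
  p <- p_from_z(z_null)
  r <- data.frame(snp = sprintf("s%04d", 1:n_snps), beta_int = sign(z_null),
                  se = 1, t = z_null, p = p, n_used = 500,
                  direction = ifelse(z_null >= 0, "+", "-"), note = "",
                  stringsAsFactors = FALSE)
  m <- meta_analyze(r, r, genomic_control = TRUE)
  lam <- attr(m, "lambda")
  expect_equal(unname(lam["study1"]), 1, tolerance = 0.05)
})

test_that("allele harmonization flips swapped strands and drops mismatches", {
  r <- data.frame(snp = c("a", "b", "c"), beta_int = c(1, 1, 1), se = 1,
                  t = 2, p = 0.04, n_used = 100, direction = "+", note = "",
                  stringsAsFactors = FALSE)
  meta1 <- data.frame(snp = c("a", "b", "c"), A1 = c("A", "A", "A"),
                      A2 = c("G", "G", "G"))
  meta2 <- data.frame(snp = c("a", "b", "c"), A1 = c("A", "G", "C"),
                      A2 = c("G", "A", "T"))
  expect_warning(m <- meta_analyze(r, r, meta1, meta2,
                                   genomic_control = FALSE), "incompatible")
  expect_false("c" %in% m$snp)
  expect_equal(m$direction[m$snp == "b"], "+-")   # flipped second study
  expect_equal(m$z_meta[m$snp == "b"], 0, tolerance = 1e-12)
})

test_that("direction filter keeps concordant SNPs only", {
  meta <- data.frame(snp = c("a", "b", "c"), z1 = 1, z2 = 1,
                     z_meta = c(3, 2, 1), p_meta = c(0.001, 0.04, 0.3),
                     direction = c("++", "+-", "--"), N = 100,
                     q = NA_real_, stringsAsFactors = FALSE)
  out <- direction_filter(meta)
  expect_setequal(out$snp, c("a", "c"))
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- direction_filter(meta[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("SNP-to-gene mapping uses 1-based inclusive boundaries", {
  bounds <- data.frame(gene = c("G1", "G2", "G3"),
                       chrom = c("2", "2", "3"),
                       start = c(100L, 150L, 100L), end = c(200L, 250L, 200L))
  snps <- data.frame(snp = c("s_start", "s_end1", "s_over"),
                     chrom = c("2", "2", "2"),
                     pos = c(100L, 251L, 180L))
  mp <- map_snps_to_genes(snps, bounds)
  expect_equal(mp$s_start, "G1")              # position == start, inclusive
  expect_length(mp$s_end1, 0)                 # position == end + 1
  expect_setequal(mp$s_over, c("G1", "G2"))   # overlapping genes: both
  snps2 <- data.frame(snp = "x", chrom = "2", pos = 150L)
  bounds2 <- data.frame(gene = "G3", chrom = "3", start = 100L, end = 200L)
  expect_length(map_snps_to_genes(snps2, bounds2)$x, 0)
})

test_that("q-values follow the BH formula and Z/p conversions round-trip", {
  expect_equal(fdr_qvalues(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(fdr_qvalues(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9),
               tolerance = 1e-12)
  p <- c(0.2, 0.01, 0.6, 0.04)
  q <- fdr_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  qs <- fdr_qvalues(p, method = "storey")
  expect_true(all(qs <= fdr_qvalues(p) + 1e-12))

  expect_equal(p_from_z(0), 1)
  zz <- c(-4.1, -1.2, 0.3, 2.8)
  expect_equal(z_from_p(p_from_z(zz), sign(zz)), zz, tolerance = 1e-10)
})

test_that("LD summary recovers perfect and absent disequilibrium", {
  set.seed(77)
  h <- rbinom(400, 1, 0.4)                    # haplotype allele
  d1 <- h[1:200] + h[201:400]                 # same haplotypes at both loci
  ld <- ld_summary(d1, d1)
  expect_equal(unname(ld["r2"]), 1, tolerance = 1e-6)
  expect_equal(unname(ld["dprime"]), 1, tolerance = 1e-6)
  d2 <- rbinom(200, 2, 0.4)
  ld0 <- ld_summary(d1, d2)
  expect_lt(unname(ld0["r2"]), 0.05)
})

test_that("planted interaction SNPs are strongly enriched at the top of the meta ranking", {
  # At a 0.8 y/unit effect with AAO noise of 5 y and N = 600 + 600, each
  # planted SNP carries a per-study z near 1.8 (meta z ~ 2.6), so planted
  # SNPs concentrate in the extreme tail of a 2000-SNP panel without
  # occupying the very top ranks.
  med_frac <- vapply(1:10, function(s) {
    cfg1 <- geno_sim_config(maf_range = c(0.3, 0.3), seed = 400 + s)
    cfg2 <- geno_sim_config(maf_range = c(0.3, 0.3), seed = 500 + s)
    cos <- simulate_cohorts(cfg1, cfg2)
    r1 <- interaction_scan(qc(cos[[1]])$cohort)
    r2 <- interaction_scan(qc(cos[[2]])$cohort)
    meta <- meta_analyze(r1, r2)
    planted <- attr(cos, "planted_snps")
    stats::median(match(planted, meta$snp)) / nrow(meta)
  }, numeric(1))
  # under no enrichment the median planted rank fraction centers on 0.5;
  # planted SNPs should sit deep in the upper tail in nearly every seed
  expect_gte(sum(med_frac <= 0.25), 8)
  expect_lt(mean(med_frac), 0.15)
})
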