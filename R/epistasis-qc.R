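#' Genotype quality control
#'
#' Applies the standard GWAS filters in a fixed order: sample call rate
#' first, then (on the retained samples) SNP autosome membership, SNP call
#' rate and minor allele frequency.
#'
#' @param cohort a [genotype_cohort()].
#' @param snp_call minimum SNP call rate; SNPs strictly below are removed.
#' @param maf minimum minor allele frequency; SNPs strictly below are removed.
#' @param sample_call minimum sample call rate.
#' @param autosomes_only drop SNPs whose chromosome is not 1..22.
#' @return List with `cohort` (filtered) and `report` (a `qc_report` listing
#'   removals per rule and before/after counts).
#' @export
qc <- function(cohort, snp_call = 0.95, maf = 0.05, sample_call = 0.95,
               autosomes_only = TRUE) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  dos <- cohort$dosage
  n0 <- nrow(dos); m0 <- ncol(dos)

  samp_cr <- rowMeans(!is.na(dos))
  bad_samples <- rownames(dos)[samp_cr < sample_call]
  keep_s <- setdiff(rownames(dos), bad_samples)
  dos <- dos[keep_s, , drop = FALSE]

  chrom <- cohort$snp_meta$chrom[match(colnames(dos), cohort$snp_meta$snp)]
  non_auto <- colnames(dos)[autosomes_only & !(chrom %in% as.character(1:22))]

  snp_cr <- colMeans(!is.na(dos))
  low_call <- colnames(dos)[snp_cr < snp_call]

  freq <- colMeans(dos, na.rm = TRUE) / 2
  mafs <- pmin(freq, 1 - freq)
  low_maf <- colnames(dos)[is.nan(mafs) | mafs < maf]

  drop_snps <- unique(c(non_auto, low_call, low_maf))
  keep_m <- setdiff(colnames(dos), drop_snps)
  out <- genotype_cohort(dos[, keep_m, drop = FALSE],
                         cohort$snp_meta[cohort$snp_meta$snp %in% keep_m, ,
                                         drop = FALSE],
                         cohort$pheno[cohort$pheno$sample_id %in% keep_s, ,
                                      drop = FALSE])
  attr(out, "planted_snps") <- attr(cohort, "planted_snps")
  report <- structure(list(
    rule_order = c("sample_call_rate", "non_autosome", "snp_call_rate", "maf"),
    samples_removed = bad_samples,
    snps_non_autosome = non_auto,
    snps_low_call = low_call,
    snps_low_maf = low_maf,
    n_samples = c(before = n0, after = length(keep_s)),
    n_snps = c(before = m0, after = length(keep_m))),
    class = "qc_report")
  list(cohort = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: samples", x$n_samples["before"], "->", x$n_samples["after"],
      "; SNPs", x$n_snps["before"], "->", x$n_snps["after"], "\n")
  cat("  removed: ", length(x$samples_removed), " samples (call rate), ",
      length(x$snps_non_autosome), " non-autosomal, ",
      length(x$snps_low_call), " low call rate, ",
      length(x$snps_low_maf), " low MAF SNPs\n", sep = "")
  invisible(x)
}

#' Multidimensional-scaling ancestry covariates
#'
#' Classical metric MDS (principal coordinates) of the pairwise
#' allele-sharing distance `1 - IBS`, where IBS between two samples is the
#' mean over their jointly non-missing SNPs of `(2 - |d_i - d_j|) / 2`. Axis
#' signs follow a deterministic convention: on each axis the sample with the
#' largest absolute coordinate is made positive. Samples beyond
#' `outlier_sd` standard deviations on any axis are flagged.
#'
#' @param cohort a [genotype_cohort()] (typically post-QC).
#' @param n_axes number of coordinates returned; default 3.
#' @param outlier_sd outlier flag threshold in SDs; default 6.
#' @return Data frame with `sample_id` and columns `MDS1..MDSk`; attribute
#'   `outliers` lists flagged sample ids.
#' @export
mds_covariates <- function(cohort, n_axes = 3L, outlier_sd = 6) {
  dos <- cohort$dosage
  n <- nrow(dos)
  obs <- !is.na(dos)
  X <- dos; X[!obs] <- 0
  M <- obs * 1
  # |di - dj| decomposes over dosage indicator matrices
  I0 <- (X == 0 & obs) * 1; I1 <- (X == 1 & obs) * 1; I2 <- (X == 2 & obs) * 1
  S <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1) +
    2 * (I0 %*% t(I2) + I2 %*% t(I0))
  C <- M %*% t(M)                     # jointly observed SNP counts
  if (any(C == 0)) stop("sample pair with no jointly observed SNPs",
                        call. = FALSE)
  overlap_frac <- C / ncol(dos)
  if (mean(overlap_frac < 0.8) > 0.2)
    warning("more than 20% of sample pairs share < 80% of SNPs", call. = FALSE)
  D <- S / (2 * C)                    # 1 - IBS
  diag(D) <- 0
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n_axes))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  if (ncol(coords) < n_axes)   # degenerate geometry: pad with zero axes
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  for (j in seq_len(ncol(coords))) {
    i_star <- which.max(abs(coords[, j]))
    if (coords[i_star, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  out <- data.frame(sample_id = rownames(dos), coords,
                    stringsAsFactors = FALSE, row.names = NULL)
  zs <- scale(coords)
  flagged <- rownames(dos)[apply(abs(zs) > outlier_sd, 1L, any)]
  attr(out, "outliers") <- flagged
  out
}

#' Composite linkage-disequilibrium summary for a SNP pair
#'
#' Estimates two-locus haplotype frequencies from unphased dosages by the
#' standard EM split of double heterozygotes, then reports `r2` and `D'`.
#'
#' @param d1,d2 dosage vectors in `{0,1,2}` (NA allowed) for the two SNPs.
#' @param max_iter,tol EM controls.
#' @return Named numeric vector with `r2`, `dprime` and `D`.
#' @export
ld_summary <- function(d1, d2, max_iter = 100L, tol = 1e-10) {
  ok <- !is.na(d1) & !is.na(d2)
  a <- d1[ok]; b <- d2[ok]
  n <- length(a)
  if (n < 2L) stop("need >= 2 complete genotype pairs", call. = FALSE)
  pA <- mean(a) / 2; pB <- mean(b) / 2
  # haplotypes: 11, 10, 01, 00 ("1" = counted allele)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ndh <- sum(a == 1 & b == 1)          # double heterozygotes
  # fixed haplotype counts from unambiguous genotypes
  base <- c(`11` = sum(2 * (a == 2) * (b == 2) + (a == 2) * (b == 1) +
                         (a == 1) * (b == 2)),
            `10` = sum(2 * (a == 2) * (b == 0) + (a == 2) * (b == 1) +
                         (a == 1) * (b == 0)),
            `01` = sum(2 * (a == 0) * (b == 2) + (a == 0) * (b == 1) +
                         (a == 1) * (b == 2)),
            `00` = sum(2 * (a == 0) * (b == 0) + (a == 0) * (b == 1) +
                         (a == 1) * (b == 0)))
  for (it in seq_len(max_iter)) {
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    if (sum(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  p11 <- h[1]; pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- p11 - pA * pB
  denom_r <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom_r > 0) D^2 / denom_r else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else NA_real_
  c(r2 = unname(r2), dprime = unname(dprime), D = unname(D))
}
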