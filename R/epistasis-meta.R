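#' Sample-size-weighted Z meta-analysis of two interaction scans
#'
#' Combines per-SNP interaction results from two cohorts over their shared
#' SNPs. Each study's signed Z is recovered from its p-value and effect
#' direction, `z_i = sign(beta_i) * qnorm(1 - p_i/2)`. With genomic control
#' on, each study's Z scores are deflated by `sqrt(lambda)` where
#' `lambda = median(z^2) / qchisq(0.5, 1)` floored at 1. The combined
#' statistic is `z_meta = (w1 z1 + w2 z2) / sqrt(w1^2 + w2^2)` with
#' `w_i = sqrt(N_i)` (per-SNP sample sizes), and
#' `p_meta = 2 * Phi(-|z_meta|)`.
#'
#' When both cohorts' SNP metadata are supplied, allele orientation is
#' harmonized: SNPs typed on swapped alleles have the second study's Z sign
#' flipped; SNPs with incompatible alleles are dropped with a warning.
#'
#' @param res1,res2 [interaction_scan()] results for the two cohorts.
#' @param meta1,meta2 optional `snp_meta` data frames (columns `snp`, `A1`,
#'   `A2`) used for allele harmonization.
#' @param genomic_control apply per-study lambda correction; default `TRUE`.
#' @return Data frame with one row per shared SNP: `snp`, `z1`, `z2`,
#'   `z_meta`, `p_meta`, `direction` (e.g. `"++"`), `N` (total sample size),
#'   `q` (BH). Attribute `lambda` holds the two inflation factors.
#' @export
meta_analyze <- function(res1, res2, meta1 = NULL, meta2 = NULL,
                         genomic_control = TRUE) {
  shared <- intersect(res1$snp, res2$snp)
  r1 <- res1[match(shared, res1$snp), , drop = FALSE]
  r2 <- res2[match(shared, res2$snp), , drop = FALSE]
  flip <- rep(1, length(shared))
  if (!is.null(meta1) && !is.null(meta2)) {
    a1 <- meta1[match(shared, meta1$snp), c("A1", "A2")]
    a2 <- meta2[match(shared, meta2$snp), c("A1", "A2")]
    same <- a1$A1 == a2$A1 & a1$A2 == a2$A2
    swapped <- a1$A1 == a2$A2 & a1$A2 == a2$A1
    bad <- !(same | swapped)
    flip[swapped] <- -1
    if (any(bad, na.rm = TRUE)) {
      warning(sum(bad, na.rm = TRUE),
              " SNPs dropped: incompatible alleles across cohorts",
              call. = FALSE)
      keep <- !bad
      shared <- shared[keep]; r1 <- r1[keep, ]; r2 <- r2[keep, ]
      flip <- flip[keep]
    }
  }
  ok <- !is.na(r1$p) & !is.na(r2$p)
  shared <- shared[ok]; r1 <- r1[ok, ]; r2 <- r2[ok, ]; flip <- flip[ok]

  z1 <- z_from_p(r1$p, ifelse(r1$beta_int >= 0, 1, -1))
  z2 <- z_from_p(r2$p, ifelse(r2$beta_int >= 0, 1, -1)) * flip
  lambda <- c(study1 = 1, study2 = 1)
  if (genomic_control) {
    lambda["study1"] <- max(1, stats::median(z1^2) / stats::qchisq(0.5, 1))
    lambda["study2"] <- max(1, stats::median(z2^2) / stats::qchisq(0.5, 1))
    z1 <- z1 / sqrt(lambda["study1"])
    z2 <- z2 / sqrt(lambda["study2"])
  }
  w1 <- sqrt(r1$n_used); w2 <- sqrt(r2$n_used)
  z_meta <- (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
  p_meta <- p_from_z(z_meta)
  dir_chr <- function(z) ifelse(z >= 0, "+", "-")
  out <- data.frame(snp = shared, z1 = z1, z2 = z2, z_meta = z_meta,
                    p_meta = p_meta,
                    direction = paste0(dir_chr(z1), dir_chr(z2)),
                    N = r1$n_used + r2$n_used,
                    q = fdr_qvalues(p_meta),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lambda") <- lambda
  out[order(out$p_meta, out$snp), , drop = FALSE]
}

#' Keep SNPs with a concordant direction of effect
#'
#' Retains meta-analysis rows whose per-study effect signs agree (direction
#' `"++"` or `"--"`); the number removed is reported in attribute `n_removed`.
#' Q-values are recomputed on the retained set, since that is the set taken
#' forward to significance calls.
#'
#' @param meta a [meta_analyze()] result.
#' @return The concordant subset, same columns, `q` recomputed.
#' @export
direction_filter <- function(meta) {
  keep <- meta$direction %in% c("++", "--")
  out <- meta[keep, , drop = FALSE]
  if (nrow(out)) out$q <- fdr_qvalues(out$p_meta)
  attr(out, "n_removed") <- sum(!keep)
  out
}
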