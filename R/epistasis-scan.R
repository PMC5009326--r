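#' Per-SNP APOE-by-SNP interaction regression on age-at-onset
#'
#' For each SNP, fits ordinary least squares
#' `AAO ~ 1 + APOE4 + dosage + APOE4:dosage [+ covariates]` on the samples
#' with observed dosage, and reports the interaction coefficient (years per
#' APOE4-by-dosage unit), its standard error, t statistic and two-sided
#' p-value from the t distribution with residual degrees of freedom.
#' Rank-deficient designs (e.g. a monomorphic SNP) yield an `NA` row flagged
#' in the `note` column rather than being dropped.
#'
#' @param cohort a [genotype_cohort()] (post-QC).
#' @param covariates optional data frame with `sample_id` plus numeric
#'   columns (e.g. [mds_covariates()] output) entering the model additively.
#' @param min_complete minimum complete cases per SNP; default 10.
#' @return Data frame with one row per SNP: `snp`, `beta_int`, `se`, `t`,
#'   `p`, `n_used`, `direction` (sign of `beta_int`), `note`.
#' @export
interaction_scan <- function(cohort, covariates = NULL, min_complete = 10L) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  dos <- cohort$dosage
  ph <- cohort$pheno
  y_all <- ph$aao
  apoe_all <- ph$apoe4
  covmat <- NULL
  if (!is.null(covariates)) {
    idx <- match(ph$sample_id, covariates$sample_id)
    if (anyNA(idx)) stop("covariates missing for some samples", call. = FALSE)
    covmat <- as.matrix(covariates[idx, setdiff(names(covariates),
                                                "sample_id"), drop = FALSE])
  }
  snps <- colnames(dos)
  out <- data.frame(snp = snps, beta_int = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, n_used = NA_integer_,
                    direction = NA_character_, note = "",
                    stringsAsFactors = FALSE)
  for (j in seq_along(snps)) {
    d <- dos[, j]
    ok <- !is.na(d) & !is.na(y_all) & !is.na(apoe_all)
    n <- sum(ok)
    out$n_used[j] <- n
    if (n < min_complete) { out$note[j] <- "too_few_complete"; next }
    X <- cbind(1, apoe_all[ok], d[ok], apoe_all[ok] * d[ok])
    if (!is.null(covmat)) X <- cbind(X, covmat[ok, , drop = FALSE])
    fit <- ols_interaction(X, y_all[ok], term = 4L)
    if (is.null(fit)) { out$note[j] <- "collinear"; next }
    out$beta_int[j] <- fit["beta"]
    out$se[j] <- fit["se"]
    out$t[j] <- fit["t"]
    out$p[j] <- fit["p"]
    out$direction[j] <- if (fit["beta"] >= 0) "+" else "-"
  }
  out
}

# OLS of y on X returning the coefficient at column `term` with its SE,
# t and two-sided p; NULL when the design is rank-deficient.
ols_interaction <- function(X, y, term) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df < 1L) return(NULL)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[term, term])
  tval <- beta[term] / se
  c(beta = unname(beta[term]), se = se, t = unname(tval),
    p = 2 * stats::pt(-abs(unname(tval)), df))
}

#' Two-sided p-value from a Z score, and back
#'
#' `p_from_z` gives `2 * Phi(-|z|)`; `z_from_p` inverts it with an explicit
#' sign. The two are consistent to better than 1e-10 on a round trip.
#'
#' @param z numeric Z score(s).
#' @return `p_from_z`: two-sided p-value(s) in `(0, 1]`.
#' @export
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' @rdname p_from_z
#' @param p two-sided p-value(s).
#' @param sign sign(s) of the effect, `+1` or `-1`.
#' @return `z_from_p`: signed Z score(s).
#' @export
z_from_p <- function(p, sign = 1) sign * stats::qnorm(p / 2,
                                                      lower.tail = FALSE)

#' Map SNPs to genes by position
#'
#' A SNP maps to every gene whose `[start, end]` interval (1-based,
#' inclusive at both ends) contains the SNP position on the same chromosome;
#' overlapping genes give multiple assignments.
#'
#' @param snp_meta data frame with `snp`, `chrom`, `pos`.
#' @param boundaries data frame with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; `start <= end`).
#' @return Named list mapping each SNP id to a character vector of genes
#'   (possibly empty).
#' @export
map_snps_to_genes <- function(snp_meta, boundaries) {
  if (any(boundaries$start > boundaries$end))
    stop("gene boundaries must satisfy start <= end", call. = FALSE)
  out <- vector("list", nrow(snp_meta))
  names(out) <- snp_meta$snp
  for (i in seq_len(nrow(snp_meta))) {
    hit <- boundaries$chrom == snp_meta$chrom[i] &
      boundaries$start <= snp_meta$pos[i] &
      boundaries$end >= snp_meta$pos[i]
    out[[i]] <- boundaries$gene[hit]
  }
  out
}

#' FDR q-values
#'
#' Benjamini-Hochberg by default; `method = "storey"` additionally scales by
#' an estimated null proportion `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p numeric vector of p-values.
#' @param method `"BH"` or `"storey"`.
#' @return Numeric q-values, same length and order as `p`.
#' @export
fdr_qvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}
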