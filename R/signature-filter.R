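#' Wilcoxon rank-sum probe filter
#'
#' Computes a two-sided rank-sum p-value per probe between the two sample
#' groups and retains probes with `p <= alpha_filter`. The exact null
#' distribution is used when there are no ties and at most 50 samples;
#' otherwise the normal approximation with tie correction and continuity
#' correction is applied (matching [stats::wilcox.test()]). Constant probes
#' get `p = 1`.
#'
#' @param ds an [expression_dataset()].
#' @param alpha_filter retention threshold in `(0, 1]`.
#' @return List with `retained` (probe ids with `p <= alpha_filter`, sorted by
#'   probe id) and `pvalues` (named vector over all probes).
#' @export
wilcoxon_filter <- function(ds, alpha_filter = 0.01) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (alpha_filter <= 0 || alpha_filter > 1)
    stop("alpha_filter must be in (0, 1]", call. = FALSE)
  g <- ds$group_labels
  lv <- sort(unique(g))
  ia <- which(g == lv[1L]); ib <- which(g == lv[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  p <- rank_sum_pvalues(ds$abundance, ia, ib)
  names(p) <- ds$probe_ids
  retained <- sort(ds$probe_ids[p <= alpha_filter])
  list(retained = retained, pvalues = p)
}

# Per-row rank precomputation: ranks are label-free, so permutation tests
# can reuse them across label reshuffles.
precompute_ranksum <- function(mat) {
  rk <- t(apply(mat, 1L, rank))
  has_ties <- apply(mat, 1L, anyDuplicated) > 0
  tiesum <- numeric(nrow(mat))
  if (any(has_ties)) {
    tiesum[has_ties] <- vapply(which(has_ties), function(i) {
      tt <- tabulate(match(mat[i, ], unique(mat[i, ])))
      sum(tt^3 - tt)
    }, numeric(1))
  }
  list(rk = rk, has_ties = has_ties, tiesum = tiesum, n = ncol(mat))
}

# Two-sided rank-sum p-values for group columns `ia` (vs the rest), from a
# precompute_ranksum() object. Exact null distribution when tie-free and
# n <= 50; normal approximation with tie and continuity correction otherwise.
ranksum_pvalues <- function(pre, ia) {
  n <- pre$n
  na <- length(ia); nb <- n - na
  W <- rowSums(pre$rk[, ia, drop = FALSE]) - na * (na + 1) / 2  # U statistic
  p <- numeric(nrow(pre$rk))
  exact_ok <- !pre$has_ties & n <= 50L
  if (any(exact_ok)) {
    u <- W[exact_ok]
    p_lo <- stats::pwilcox(u, na, nb)
    p_hi <- stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p[exact_ok] <- pmin(1, 2 * pmin(p_lo, p_hi))
  }
  if (any(!exact_ok)) {
    idx <- which(!exact_ok)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - pre$tiesum[idx] / (n * (n - 1)))
    z <- W[idx] - mu
    zero <- sig2 <= 0          # constant probe
    cc <- sign(z) * 0.5        # continuity correction
    zstat <- ifelse(zero, 0, (z - cc) / sqrt(pmax(sig2, 1e-300)))
    p[idx] <- ifelse(zero, 1, pmin(1, 2 * stats::pnorm(-abs(zstat))))
  }
  p
}

# Vectorised two-sided rank-sum p-values for every row of `mat`,
# group columns ia vs ib.
rank_sum_pvalues <- function(mat, ia, ib) {
  pre <- precompute_ranksum(mat[, c(ia, ib), drop = FALSE])
  ranksum_pvalues(pre, seq_along(ia))
}

#' Rank the probes of one sample
#'
#' Probes are sorted by descending abundance within the sample; ties are
#' broken by ascending probe id so the ranking is deterministic across
#' platforms.
#'
#' @param ds an [expression_dataset()].
#' @param retained character vector of probe ids to rank (the filter output).
#' @param sample_id sample to rank.
#' @return Character vector of probe ids, highest abundance first.
#' @export
rank_sample <- function(ds, retained, sample_id) {
  x <- ds$abundance[retained, sample_id]
  retained[order(-x, retained, method = "radix")]
}

# Rankings for all samples at once; list named by sample id.
rank_all_samples <- function(ds, retained) {
  sub <- ds$abundance[retained, , drop = FALSE]
  out <- lapply(seq_len(ncol(sub)), function(j)
    retained[order(-sub[, j], retained, method = "radix")])
  names(out) <- ds$sample_ids
  out
}

#' Build a per-sample signature from a ranking
#'
#' @param ranked ordered probe ids (highest first), as from [rank_sample()].
#' @param n1 number of top probes.
#' @param n2 number of bottom probes.
#' @return A `sample_signature`: list with `top` (first `n1` ids) and `bottom`
#'   (last `n2` ids, lowest-ranked last).
#' @export
build_signature <- function(ranked, n1, n2) {
  n <- length(ranked)
  if (n1 < 1L || n2 < 1L) stop("n1 and n2 must be >= 1", call. = FALSE)
  if (n1 + n2 > n)
    stop("n1 + n2 exceeds the number of ranked probes", call. = FALSE)
  structure(list(top = ranked[seq_len(n1)],
                 bottom = ranked[seq.int(n - n2 + 1L, n)]),
            class = "sample_signature")
}

#' Extract the transcriptional biomarker
#'
#' The biomarker is the union of all probes included in at least one sample
#' signature, together with the genes they map to — the smallest probe set the
#' classifier actually uses.
#'
#' @param signatures list of `sample_signature` objects.
#' @param probe_to_gene named character vector, probe id to gene symbol.
#' @param pvalues named vector of filter p-values.
#' @return A `biomarker`: list with `probe_ids`, `gene_symbols` and
#'   `filter_pvalues` restricted to the biomarker probes.
#' @export
extract_biomarker <- function(signatures, probe_to_gene, pvalues) {
  probes <- sort(unique(unlist(lapply(signatures,
                                      function(s) c(s$top, s$bottom)))))
  genes <- sort(unique(unname(probe_to_gene[probes])))
  structure(list(probe_ids = probes,
                 gene_symbols = genes,
                 gene_of = probe_to_gene[probes],
                 filter_pvalues = pvalues[probes]),
            class = "biomarker")
}

#' @export
print.biomarker <- function(x, ...) {
  cat("biomarker:", length(x$probe_ids), "probes /",
      length(x$gene_symbols), "genes\n")
  invisible(x)
}

#' Gene-level p-values for a biomarker
#'
#' Collapses probe-level filter p-values to genes (minimum p per gene), the
#' form consumed by network node scoring.
#'
#' @param biomarker a [extract_biomarker()] result.
#' @return Named numeric vector of p-values over `gene_symbols`.
#' @export
biomarker_gene_pvalues <- function(biomarker) {
  gp <- tapply(biomarker$filter_pvalues, unname(biomarker$gene_of), min)
  stats::setNames(as.numeric(gp), names(gp))
}
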