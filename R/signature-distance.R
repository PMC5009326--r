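#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Signed maximum deviation of the weighted running sum of a probe set against
#' a ranked probe list (the GSEA-style statistic). Walking down the ranking,
#' hits accumulate weight `|position score|^weight_exponent`, where the
#' position score at rank `i` of `N` is the centered rank `(N + 1)/2 - i`
#' (positive at the top of the list, negative at the bottom); misses
#' accumulate uniformly. The score is the deviation of largest magnitude,
#' in `[-1, 1]`: +1 when the whole set sits at the very top of the ranking,
#' -1 at the very bottom. `weight_exponent = 0` recovers the classic
#' unweighted KS statistic.
#'
#' @param set character vector of probe ids, a subset of `ranking`.
#' @param ranking ordered probe ids (highest-ranked first).
#' @param weight_exponent nonnegative weighting exponent; default 1.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
enrichment_score <- function(set, ranking, weight_exponent = 1) {
  pos <- match(set, ranking)
  pos <- sort(pos[!is.na(pos)])
  es_from_positions(pos, length(ranking), weight_exponent)
}

# Core enrichment score from sorted hit positions. The running deviation
# P_hit - P_miss attains its maximum at hit positions and its minimum just
# before them, so only 2k candidate deviations need to be examined.
es_from_positions <- function(pos, N, weight_exponent = 1) {
  k <- length(pos)
  if (k == 0L || N == 0L) return(0)
  w <- abs((N + 1) / 2 - pos)^weight_exponent
  denom <- sum(w)
  if (denom <= 0) { w <- rep(1, k); denom <- k }
  cumw <- cumsum(w)
  n_miss <- N - k
  i <- seq_len(k)
  if (n_miss > 0L) {
    dev_at <- cumw / denom - (pos - i) / n_miss
    dev_before <- c(0, cumw[-k]) / denom - (pos - i) / n_miss
  } else {
    dev_at <- cumw / denom
    dev_before <- c(0, cumw[-k]) / denom
  }
  hi <- which.max(dev_at); lo <- which.min(dev_before)
  M <- dev_at[hi]; m <- dev_before[lo]
  if (abs(M) > abs(m)) return(M)
  if (abs(m) > abs(M)) return(m)
  # equal magnitude: take the deviation reached first along the ranking
  if (pos[lo] - 1L < pos[hi]) m else M
}

#' Enrichment-score distance between two sample signatures
#'
#' Measures how dissimilar two samples' expression profiles are by asking
#' where each sample's top and bottom signature probes fall in the other
#' sample's full ranking. Each sample contributes a concordance
#' `c = (ES(top) - ES(bottom)) / 2` in `[-1, 1]` (+1 when the other ranking
#' places the top probes at its top and the bottom probes at its bottom), and
#' the distance is `d = 1 - (c_A + c_B + 2) / 4`, which is symmetric, lies in
#' `[0, 1]`, equals 0 for identical rankings and 1 for perfectly
#' anti-correlated ones.
#'
#' @param sigA,sigB `sample_signature` objects from [build_signature()],
#'   built over the same retained probe universe.
#' @param rankedA,rankedB full rankings of the two samples over that universe.
#' @param weight_exponent passed to [enrichment_score()].
#' @return Numeric distance in `[0, 1]`.
#' @export
signature_distance <- function(sigA, sigB, rankedA, rankedB,
                               weight_exponent = 1) {
  if (length(rankedA) != length(rankedB) ||
      !all(sort(rankedA) == sort(rankedB)))
    stop("signatures were built over different probe universes", call. = FALSE)
  cA <- (enrichment_score(sigA$top, rankedB, weight_exponent) -
           enrichment_score(sigA$bottom, rankedB, weight_exponent)) / 2
  cB <- (enrichment_score(sigB$top, rankedA, weight_exponent) -
           enrichment_score(sigB$bottom, rankedA, weight_exponent)) / 2
  1 - (cA + cB + 2) / 4
}

# Internal distance kernel on integer rank positions: `sub` is the
# retained-probe x sample abundance matrix. Signatures are row indices; the
# concordance of sample i's signature against sample j's ranking uses only
# the positions of those indices in j's order, so the whole all-pairs
# computation vectorizes as k x (S^2) matrix operations.
rank_positions <- function(sub) {
  N <- nrow(sub); S <- ncol(sub)
  ids <- rownames(sub)
  ords <- vector("list", S)
  pos <- matrix(0L, N, S)
  for (j in seq_len(S)) {
    o <- order(-sub[, j], ids, method = "radix")
    ords[[j]] <- o
    pos[o, j] <- seq_len(N)
  }
  list(ords = ords, pos = pos, N = N)
}

# Batched enrichment scores: `posmat` is k x P, each column the (unsorted)
# rank positions of one k-probe set in one ranking of length N. Returns the
# length-P vector of signed maximum-deviation scores.
es_columns <- function(posmat, N, weight_exponent) {
  k <- nrow(posmat); P <- ncol(posmat)
  # sort each column with a single radix pass
  o <- order(col(posmat), posmat, method = "radix")
  sp <- matrix(posmat[o], k, P)
  w <- abs((N + 1) / 2 - sp)^weight_exponent
  denom <- .colSums(w, k, P)
  bad <- denom <= 0
  if (any(bad)) { w[, bad] <- 1; denom[bad] <- k }
  cw <- w
  if (k > 1L) for (r in seq.int(2L, k)) cw[r, ] <- cw[r - 1L, ] + w[r, ]
  i_row <- matrix(seq_len(k), k, P)
  n_miss <- N - k
  if (n_miss > 0L) {
    miss_frac <- (sp - i_row) / n_miss
    dev_at <- sweep(cw, 2L, denom, "/") - miss_frac
    dev_before <- sweep(cw - w, 2L, denom, "/") - miss_frac
  } else {
    dev_at <- sweep(cw, 2L, denom, "/")
    dev_before <- sweep(cw - w, 2L, denom, "/")
  }
  M <- dev_at[1L, ]; m <- dev_before[1L, ]
  if (k > 1L) for (r in seq.int(2L, k)) {
    M <- pmax(M, dev_at[r, ]); m <- pmin(m, dev_before[r, ])
  }
  es <- ifelse(abs(M) >= abs(m), M, m)
  ties <- which(abs(abs(M) - abs(m)) < 1e-15 & M != m)
  for (p in ties)   # rare: defer to the scalar rule (first-reached deviation)
    es[p] <- es_from_positions(sp[, p], N, weight_exponent)
  es
}

# Full S x S distance matrix from a rank_positions() object.
kernel_distances <- function(rp, n1, n2, weight_exponent) {
  N <- rp$N
  S <- length(rp$ords)
  tops_mat <- vapply(rp$ords, function(o) o[seq_len(n1)], integer(n1))
  bots_mat <- vapply(rp$ords, function(o) o[seq.int(N - n2 + 1L, N)],
                     integer(n2))
  tops_mat <- matrix(tops_mat, n1, S)
  bots_mat <- matrix(bots_mat, n2, S)
  # column (j-1)*S + i holds sample i's set positions in ranking j
  top_pos <- matrix(rp$pos[as.vector(tops_mat), , drop = FALSE], n1, S * S)
  bot_pos <- matrix(rp$pos[as.vector(bots_mat), , drop = FALSE], n2, S * S)
  conc <- matrix((es_columns(top_pos, N, weight_exponent) -
                    es_columns(bot_pos, N, weight_exponent)) / 2, S, S)
  1 - (conc + t(conc) + 2) / 4
}

#' All-to-all signature distance matrix
#'
#' Builds per-sample rankings and signatures over the retained probes and
#' computes the symmetric enrichment-score distance between every pair of
#' samples. Entries lie in `[0, 1]` with a zero diagonal.
#'
#' @param ds an [expression_dataset()].
#' @param retained probe ids surviving [wilcoxon_filter()].
#' @param n1,n2 signature lengths (same for every sample).
#' @param weight_exponent passed to [enrichment_score()].
#' @return List with `D` (sample-by-sample matrix), `signatures` and
#'   `rankings` (both per-sample lists).
#' @export
distance_matrix <- function(ds, retained, n1, n2, weight_exponent = 1) {
  sub <- ds$abundance[retained, , drop = FALSE]
  rp <- rank_positions(sub)
  D <- kernel_distances(rp, n1, n2, weight_exponent)
  dimnames(D) <- list(ds$sample_ids, ds$sample_ids)
  rankings <- lapply(rp$ords, function(o) retained[o])
  names(rankings) <- ds$sample_ids
  sigs <- lapply(rankings, build_signature, n1 = n1, n2 = n2)
  list(D = D, signatures = sigs, rankings = rankings)
}

# Distances between two sample index sets (used by CV: test x train).
cross_distances_kernel <- function(sub, n1, n2, test_idx, train_idx,
                                   weight_exponent = 1) {
  rp <- rank_positions(sub)
  D <- kernel_distances(rp, n1, n2, weight_exponent)
  D <- D[test_idx, train_idx, drop = FALSE]
  dimnames(D) <- list(colnames(sub)[test_idx], colnames(sub)[train_idx])
  D
}
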