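#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols). Duplicate
#'   genes within a set are removed.
#' @param universe background gene list; sets are restricted to it.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list contains more of the set's
#' genes than expected under random sampling from the universe, using the
#' upper hypergeometric tail `P(X >= k)`. Query genes outside the universe
#' are dropped with a warning. P-values are Benjamini-Hochberg adjusted
#' within the collection.
#'
#' @param query character vector of genes of interest.
#' @param collection a [gene_set_collection()].
#' @param fdr_threshold rows with `q <= fdr_threshold` are flagged
#'   significant; default 0.001.
#' @return Data frame with one row per set: `set`, `k` (query-set overlap),
#'   `K` (set size), `n` (query size), `N` (universe size), `p`, `q`,
#'   `significant`; sorted by `p` then set name.
#' @export
ora <- function(query, collection, fdr_threshold = 0.001) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query", call. = FALSE)
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, collection$universe)
    if (!length(query)) stop("no query genes in the universe", call. = FALSE)
  }
  N <- length(collection$universe)
  n <- length(query)
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s, query)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set = names(collection$sets), k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q <= fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Fold-change / p-value differential-expression filter
#'
#' The simple per-gene screen used for targeted comparisons: linear-scale
#' fold change between group means combined with a two-sided Welch t-test,
#' with no multiple-testing correction in the pass/fail rule (a
#' Benjamini-Hochberg column is reported for context only). A gene passes
#' when its fold change (reported as `max(ratio, 1/ratio)` with the sign of
#' the direction) reaches `fc_threshold` and its p-value is below
#' `p_threshold`.
#'
#' @param exprA,exprB gene-by-sample matrices for the two groups, with
#'   matching row names; each group needs at least 2 samples.
#' @param fc_threshold minimum fold change; default 1.5.
#' @param p_threshold p-value cutoff; default 0.02.
#' @param log2_input set `TRUE` when the matrices are log2-scale; means are
#'   then computed on the linear scale after back-transform.
#' @return Data frame with `gene`, `fold_change` (signed: positive when
#'   group A is higher, negative when lower; magnitude always >= 1), `p`,
#'   `q_bh`, `pass`.
#' @export
de_filter <- function(exprA, exprB, fc_threshold = 1.5, p_threshold = 0.02,
                      log2_input = FALSE) {
  if (ncol(exprA) < 2L || ncol(exprB) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (!identical(rownames(exprA), rownames(exprB)))
    stop("row names of the two groups must match", call. = FALSE)
  la <- exprA; lb <- exprB
  if (log2_input) { la <- 2^exprA; lb <- 2^exprB }
  ma <- rowMeans(la); mb <- rowMeans(lb)
  ratio <- ma / mb
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)   # signed, magnitude >= 1
  p <- vapply(seq_len(nrow(exprA)), function(i) {
    if (stats::sd(exprA[i, ]) == 0 && stats::sd(exprB[i, ]) == 0) {
      if (all(exprA[i, 1] == c(exprA[i, ], exprB[i, ]))) return(1)
      return(0)
    }
    stats::t.test(exprA[i, ], exprB[i, ])$p.value
  }, numeric(1))
  pass <- abs(fc) >= fc_threshold & p < p_threshold
  data.frame(gene = rownames(exprA), fold_change = fc, p = p,
             q_bh = stats::p.adjust(p, method = "BH"), pass = pass,
             stringsAsFactors = FALSE, row.names = NULL)
}
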