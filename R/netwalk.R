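#' Assign diffusion node scores from biomarker p-values
#'
#' Biomarker genes present in the network receive `-log2(p)` of their filter
#' p-value; all other genes receive a small baseline `epsilon` that keeps the
#' restart distribution strictly positive (and hence the walk irreducible on
#' a connected graph). Scores of 0 (from `p = 1`) are floored at `epsilon`.
#'
#' @param network an igraph object with named vertices.
#' @param gene_pvalues named numeric vector of p-values per biomarker gene.
#' @param epsilon baseline score; default `1e-3` of the smallest positive
#'   biomarker score (or `1e-6` if none is positive).
#' @return Named numeric vector of scores over all network genes. Biomarker
#'   genes absent from the network are reported in attribute `missing` and a
#'   warning.
#' @export
assign_node_scores <- function(network, gene_pvalues, epsilon = NULL) {
  genes <- igraph::V(network)$name
  present <- intersect(names(gene_pvalues), genes)
  missing <- setdiff(names(gene_pvalues), genes)
  raw <- -log2(pmin(pmax(gene_pvalues[present], .Machine$double.xmin), 1))
  if (is.null(epsilon)) {
    pos <- raw[raw > 0]
    epsilon <- if (length(pos)) 1e-3 * min(pos) else 1e-6
  }
  scores <- stats::setNames(rep(epsilon, length(genes)), genes)
  scores[present] <- pmax(raw, epsilon)
  if (length(missing))
    warning(length(missing), " biomarker genes absent from the network: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...", call. = FALSE)
  attr(scores, "missing") <- missing
  scores
}

#' Random walk with restart on an interaction network
#'
#' Solves the stationary distribution `pi = (1 - r) W pi + r s`, where `W` is
#' the column-normalized adjacency matrix and `s` the node-score vector
#' normalized to sum one, by fixed-point iteration from `s`.
#'
#' @param network an igraph object with named vertices.
#' @param scores named nonnegative node scores (restart mass), covering the
#'   network's genes; missing genes get zero mass.
#' @param restart restart probability `r` in `(0, 1)`; default 0.5.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final residual.
#' @return Named numeric stationary distribution summing to one.
#' @export
random_walk <- function(network, scores, restart = 0.5, tol = 1e-10,
                        max_iter = 10000L) {
  if (restart <= 0 || restart >= 1)
    stop("restart must be in (0, 1)", call. = FALSE)
  genes <- igraph::V(network)$name
  s <- stats::setNames(rep(0, length(genes)), genes)
  common <- intersect(names(scores), genes)
  s[common] <- scores[common]
  if (any(s < 0)) stop("scores must be nonnegative", call. = FALSE)
  if (sum(s) <= 0) stop("no positive score on any network gene", call. = FALSE)
  s <- s / sum(s)

  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::colSums(A)
  if (any(deg == 0))
    A <- A + Matrix::Diagonal(length(genes), as.numeric(deg == 0))
  W <- A %*% Matrix::Diagonal(x = 1 / Matrix::colSums(A))

  pi <- s
  for (it in seq_len(max_iter)) {
    pi_new <- as.numeric((1 - restart) * (W %*% pi) + restart * s)
    delta <- sum(abs(pi_new - pi))
    pi <- pi_new
    if (delta < tol) {
      pi <- pi / sum(pi)
      names(pi) <- genes
      attr(pi, "iterations") <- it
      return(pi)
    }
  }
  stop("random walk failed to converge: L1 residual ", signif(delta, 3),
       " after ", max_iter, " iterations", call. = FALSE)
}

#' Edge interaction scores from the weighted random walk
#'
#' The stationary flux along edge u-v is `pi(u)/deg(u) + pi(v)/deg(v)` (mass
#' traversing the edge per step in either direction). Each edge is scored as
#' `log2` of its flux under the score-weighted walk over its flux under a
#' baseline walk with uniform restart mass, so positive scores mark edges
#' carrying more diffusion mass than topology alone explains. Edges with zero
#' baseline flux receive `-Inf` and are excluded from thresholding.
#'
#' @param network an igraph object with named vertices.
#' @param scores node scores as from [assign_node_scores()].
#' @param restart restart probability.
#' @param raw_flux if `TRUE`, score edges by the weighted flux itself instead
#'   of the log-ratio to baseline.
#' @return Data frame with columns `from`, `to`, `score`, sorted by
#'   descending score.
#' @export
edge_scores <- function(network, scores, restart = 0.5, raw_flux = FALSE) {
  genes <- igraph::V(network)$name
  pw <- random_walk(network, scores, restart)
  deg <- igraph::degree(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  flux <- function(pi) pi[el[, 1L]] / deg[el[, 1L]] +
    pi[el[, 2L]] / deg[el[, 2L]]
  fw <- flux(pw)
  if (raw_flux) {
    sc <- fw
  } else {
    unif <- stats::setNames(rep(1, length(genes)), genes)
    pb <- random_walk(network, unif, restart)
    fb <- flux(pb)
    sc <- ifelse(fb > 0, log2(fw / fb), -Inf)
  }
  out <- data.frame(from = el[, 1L], to = el[, 2L], score = unname(sc),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$from, out$to), , drop = FALSE]
}

#' Detect the edge-score threshold at the step of the sorted score curve
#'
#' Sorts the finite scores in descending order and finds the largest gap
#' between consecutive scores, searching only gaps whose upper score is at or
#' above the median (a conservative choice keeping retained scores well above
#' the bulk). The threshold is the midpoint of that gap. A gap only counts as
#' an obvious step when it dominates the searched region: at least twice the
#' mean gap and at least three times the next-largest gap. When no gap
#' qualifies (near-linearly spaced scores, or a smooth decay whose largest
#' gaps are all comparable) the rule falls back to retaining the top tenth of
#' edges, with a warning. The rule is scale-equivariant: scaling all scores
#' by `c > 0` scales the threshold by `c`.
#'
#' @param scores numeric edge scores (a `score` column or vector); `-Inf`
#'   sentinels are dropped.
#' @param top_frac fallback fraction retained when no step is found.
#' @return Threshold value with attribute `method` (`"gap"` or `"top_frac"`).
#' @export
detect_threshold <- function(scores, top_frac = 0.1) {
  s <- sort(scores[is.finite(scores)], decreasing = TRUE)
  if (length(unique(s)) < 3L)
    stop("need at least 3 distinct finite scores", call. = FALSE)
  med <- stats::median(s)
  upper <- which(s[-length(s)] >= med)
  gaps <- s[upper] - s[upper + 1L]
  imax <- upper[which.max(gaps)]
  second <- if (length(gaps) > 1L) max(gaps[-which.max(gaps)]) else 0
  if (max(gaps) >= 2 * mean(gaps) && max(gaps) >= 3 * second) {
    thr <- (s[imax] + s[imax + 1L]) / 2
    attr(thr, "method") <- "gap"
  } else {
    warning("no obvious step in sorted scores; retaining top ",
            format(top_frac), " fraction of edges", call. = FALSE)
    k <- max(1L, ceiling(top_frac * length(s)))
    thr <- if (k < length(s)) (s[k] + s[k + 1L]) / 2 else s[length(s)] - 1e-12
    attr(thr, "method") <- "top_frac"
  }
  thr
}

#' Extract the above-threshold subnetwork
#'
#' Keeps edges whose score strictly exceeds the threshold and returns the
#' induced subgraph with its component structure. The largest component is
#' flagged; by default all components' genes form the gene list.
#'
#' @param network the background igraph object.
#' @param edge_table an [edge_scores()] data frame.
#' @param threshold numeric threshold (e.g. from [detect_threshold()]).
#' @param keep `"all"` to keep every above-threshold component, `"largest"`
#'   to restrict to the largest one.
#' @return A `subnetwork`: list with `graph` (igraph), `genes`, `edges` (the
#'   retained rows of `edge_table`) and `components` (sizes, largest first).
#' @export
extract_subnetwork <- function(network, edge_table, threshold,
                               keep = c("all", "largest")) {
  keep <- match.arg(keep)
  sel <- is.finite(edge_table$score) & edge_table$score > threshold
  kept <- edge_table[sel, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[, c("from", "to")], directed = FALSE,
                                     vertices = NULL)
  comp <- if (igraph::vcount(g)) igraph::components(g) else
    list(membership = integer(), csize = integer(), no = 0L)
  sizes <- sort(comp$csize, decreasing = TRUE)
  if (keep == "largest" && comp$no > 1L) {
    big <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == big))
    in_g <- kept$from %in% igraph::V(g)$name & kept$to %in% igraph::V(g)$name
    kept <- kept[in_g, , drop = FALSE]
  }
  structure(list(graph = g,
                 genes = sort(igraph::V(g)$name),
                 edges = kept,
                 components = sizes,
                 threshold = threshold),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork:", length(x$genes), "genes,", nrow(x$edges),
      "edges in", length(x$components), "component(s)\n")
  invisible(x)
}
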