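#' Configuration for the interaction-network simulator
#'
#' @param n_genes number of nodes in the background network.
#' @param attachment_parameter edges added per node during preferential
#'   attachment; controls density of the scale-free background.
#' @param planted_module_size size of the planted high-score module.
#' @param planted_overlap fraction of the informative genes placed inside the
#'   module, in `[0, 1]`.
#' @param module_mean_degree target mean intra-module degree. Functional
#'   modules are denser than the interactome background; extra intra-module
#'   edges are added until this target is reached.
#' @param seed integer seed.
#' @return An object of class `net_sim_config`.
#' @export
net_sim_config <- function(n_genes = 500L,
                           attachment_parameter = 2L,
                           planted_module_size = 50L,
                           planted_overlap = 0.8,
                           module_mean_degree = 4,
                           seed = 1L) {
  n_genes <- as.integer(n_genes)
  planted_module_size <- as.integer(planted_module_size)
  if (planted_module_size > n_genes)
    stop("planted_module_size must not exceed n_genes", call. = FALSE)
  if (planted_overlap < 0 || planted_overlap > 1)
    stop("planted_overlap must be in [0, 1]", call. = FALSE)
  if (attachment_parameter < 1)
    stop("attachment_parameter must be a positive count", call. = FALSE)
  structure(list(n_genes = n_genes,
                 attachment_parameter = as.integer(attachment_parameter),
                 planted_module_size = planted_module_size,
                 planted_overlap = planted_overlap,
                 module_mean_degree = module_mean_degree,
                 seed = as.integer(seed)),
            class = "net_sim_config")
}

#' Simulate a scale-free interaction network with a planted module
#'
#' Builds a connected preferential-attachment graph, grows a connected module
#' of the requested size by breadth-first expansion from a random seed node,
#' densifies it to `module_mean_degree`, and assigns gene symbols so that
#' `round(planted_overlap * length(informative_genes))` informative genes sit
#' inside the module and the rest outside. Remaining nodes are named from
#' `background_genes` when supplied (e.g. the expression dataset's gene
#' universe), otherwise from a fresh background namespace.
#'
#' @param cfg a [net_sim_config()].
#' @param informative_genes character vector of genes carrying planted
#'   expression signal.
#' @param background_genes optional character vector to draw non-informative
#'   node names from.
#' @return An igraph object with vertex attribute `name`; attributes
#'   `module_genes` (the planted module) and `informative_in_module`.
#' @export
simulate_network <- function(cfg, informative_genes, background_genes = NULL) {
  stopifnot(inherits(cfg, "net_sim_config"))
  if (length(informative_genes) == 0L)
    stop("informative_genes must be nonempty", call. = FALSE)
  informative_genes <- unique(informative_genes)
  withr_seed(cfg$seed, {
    g <- igraph::sample_pa(cfg$n_genes, power = 1,
                           m = cfg$attachment_parameter, directed = FALSE)
    g <- igraph::simplify(g)

    # connected module by BFS from a random start
    start <- sample(cfg$n_genes, 1L)
    bfs_order <- igraph::bfs(g, root = start, order = TRUE)$order
    module_idx <- as.integer(bfs_order[seq_len(cfg$planted_module_size)])

    # densify the module to the target mean intra-module degree
    sub <- igraph::induced_subgraph(g, module_idx)
    need <- ceiling(cfg$module_mean_degree * cfg$planted_module_size / 2) -
      igraph::ecount(sub)
    if (need > 0 && cfg$planted_module_size > 1L) {
      pairs <- utils::combn(module_idx, 2L)
      have <- igraph::get_edge_ids(g, as.vector(pairs)) > 0
      free <- which(!have)
      if (length(free)) {
        add <- free[sample.int(length(free), min(need, length(free)))]
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
      }
    }

    # gene symbol assignment
    n_in <- round(cfg$planted_overlap * length(informative_genes))
    n_in <- min(n_in, cfg$planted_module_size, length(informative_genes))
    nm <- character(cfg$n_genes)
    inside <- sample(module_idx, n_in)
    nm[inside] <- sample(informative_genes, n_in)
    outside_inf <- setdiff(informative_genes, nm[inside])
    slots <- setdiff(seq_len(cfg$n_genes), module_idx)
    n_out <- min(length(outside_inf), length(slots))
    out_slots <- if (n_out) sample(slots, n_out) else integer()
    nm[out_slots] <- outside_inf[seq_len(n_out)]

    rest <- which(nm == "")
    pool <- setdiff(background_genes, informative_genes)
    take <- min(length(pool), length(rest))
    if (take) nm[rest[seq_len(take)]] <- sample(pool, take)
    still <- which(nm == "")
    if (length(still)) nm[still] <- sprintf("BG%05d", still)
    igraph::V(g)$name <- nm

    attr(g, "module_genes") <- nm[module_idx]
    attr(g, "informative_in_module") <- nm[inside]
    g
  })
}

#' Simulate gene-set collections over a network's gene universe
#'
#' One designated set (named in attribute `true_set`) is drawn mostly from the
#' planted module; the remaining sets are drawn uniformly from the universe.
#' Used to exercise over-representation analysis with known ground truth.
#'
#' @param network an igraph object whose vertex names form the gene universe.
#' @param module character vector of module genes; source of the true set.
#' @param n_sets number of gene sets to generate.
#' @param set_size_range integer pair; set sizes are drawn uniformly from it.
#' @param true_frac fraction of the true set drawn from the module.
#' @param seed integer seed.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`; attribute `true_set` names the planted set.
#' @export
simulate_gene_sets <- function(network, module, n_sets = 50L,
                               set_size_range = c(10L, 40L),
                               true_frac = 1, seed = 1L) {
  universe <- igraph::V(network)$name
  module <- intersect(module, universe)
  if (!length(module)) stop("module has no genes in the universe", call. = FALSE)
  n_sets <- as.integer(n_sets)
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  withr_seed(seed, {
    sizes <- sample(set_size_range[1L]:set_size_range[2L], n_sets,
                    replace = TRUE)
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    k_true <- min(sizes[1L], length(module))
    n_from_module <- round(true_frac * k_true)
    true_members <- sample(module, n_from_module)
    filler <- setdiff(universe, true_members)
    extra <- k_true - n_from_module
    if (extra > 0) true_members <- c(true_members, sample(filler, extra))
    sets[[1L]] <- sort(true_members)
    for (i in seq_len(n_sets)[-1L])
      sets[[i]] <- sort(sample(universe, min(sizes[i], length(universe))))
    out <- gene_set_collection(sets, universe)
    attr(out, "true_set") <- names(sets)[1L]
    out
  })
}
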