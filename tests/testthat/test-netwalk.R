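test_that("node scores are -log2(p) with an epsilon floor and miss reporting", {
  g <- named_ring(5)
  sc <- assign_node_scores(g, c(n01 = 0.25, n02 = 1))
  expect_equal(unname(sc["n01"]), 2)                  # -log2(0.25)
  expect_equal(unname(sc["n02"]), unname(sc["n03"])) # p = 1 floored to epsilon
  expect_equal(unname(sc["n03"]), 2e-3)              # 1e-3 * min positive
  expect_warning(out <- assign_node_scores(g, c(ZZZ = 0.1)), "absent")
  expect_equal(attr(out, "missing"), "ZZZ")
})

test_that("two-node walk matches the exact linear solution", {
  g <- igraph::make_graph(~ A - B)
  pi <- random_walk(g, c(A = 1, B = 0), restart = 0.5)
  expect_equal(as.numeric(pi), c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("restart near one returns the restart vector", {
  g <- named_star(6)
  s <- c(hub = 0.1, leaf01 = 0.6, leaf02 = 0.1, leaf03 = 0.1, leaf04 = 0.05,
         leaf05 = 0.05)
  pi <- random_walk(g, s, restart = 0.999)
  expect_equal(as.numeric(pi), unname(s[names(pi)]), tolerance = 2e-3)
})

test_that("uniform restart on a regular graph is uniform", {
  g <- named_ring(6)
  pi <- random_walk(g, stats::setNames(rep(1, 6), igraph::V(g)$name), 0.5)
  expect_equal(as.numeric(pi), rep(1 / 6, 6), tolerance = 1e-9)
})

test_that("fixed point agrees with a direct linear solve on random graphs", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    g <- igraph::sample_gnp(n, 0.15)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnp(n, 0.2)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    s <- stats::runif(n); names(s) <- igraph::V(g)$name
    r <- 0.4
    pi <- random_walk(g, s, r)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    W <- A %*% diag(1 / colSums(A))
    direct <- solve(diag(n) - (1 - r) * W, r * s / sum(s))
    expect_equal(as.numeric(pi), unname(direct), tolerance = 1e-8)
    expect_equal(sum(pi), 1, tolerance = 1e-9)
    expect_true(all(pi >= 0))
  }
})

test_that("uniform scores give zero edge scores; concentration lifts incident edges", {
  g <- named_ring(8)
  u <- stats::setNames(rep(1, 8), igraph::V(g)$name)
  et <- edge_scores(g, u, 0.5)
  expect_true(all(abs(et$score) < 1e-9))

  star <- named_star(10)
  s <- stats::setNames(c(rep(1e-6, 9), 1),
                       c(setdiff(igraph::V(star)$name, "leaf09"), "leaf09"))
  et2 <- edge_scores(star, s, 0.5)
  top_edge <- et2[1, ]
  expect_true("leaf09" %in% c(top_edge$from, top_edge$to))
})

test_that("edge scores are invariant to node relabeling", {
  set.seed(5)
  g <- igraph::sample_gnp(12, 0.3)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(12, 0.3)
  igraph::V(g)$name <- sprintf("v%02d", 1:12)
  s <- stats::runif(12); names(s) <- igraph::V(g)$name
  et1 <- edge_scores(g, s, 0.5)
  perm <- sample(igraph::V(g)$name)
  g2 <- igraph::permute(g, match(perm, igraph::V(g)$name))
  et2 <- edge_scores(g2, s, 0.5)
  key <- function(df) {
    k <- apply(cbind(pmin(df$from, df$to), pmax(df$from, df$to)), 1, paste,
               collapse = "|")
    stats::setNames(df$score, k)
  }
  k1 <- key(et1); k2 <- key(et2)
  expect_equal(k1[sort(names(k1))], k2[sort(names(k1))], tolerance = 1e-9)
})

test_that("threshold detection finds a clear step and is scale-equivariant", {
  s <- c(10, 9, 8, 1, 0.5)
  thr <- detect_threshold(s)
  expect_true(thr > 1 && thr < 8)
  expect_equal(sum(s > thr), 3)
  expect_equal(attr(thr, "method"), "gap")
  thr10 <- detect_threshold(10 * s)
  expect_equal(as.numeric(thr10), 10 * as.numeric(thr), tolerance = 1e-12)

  expect_warning(flat <- detect_threshold(seq(1, 50)), "no obvious step")
  expect_equal(attr(flat, "method"), "top_frac")
  expect_error(detect_threshold(c(1, 1, 1)), "distinct")
})

test_that("subnetwork extraction respects the threshold at both extremes", {
  g <- named_ring(6)
  u <- stats::setNames(c(5, 4, 3, 2, 1, 0.5), igraph::V(g)$name)
  et <- edge_scores(g, u, 0.5, raw_flux = TRUE)
  empty <- extract_subnetwork(g, et, max(et$score) + 1)
  expect_length(empty$genes, 0)
  whole <- extract_subnetwork(g, et, min(et$score) - 1)
  expect_setequal(whole$genes, igraph::V(g)$name)
  expect_equal(nrow(whole$edges), igraph::ecount(g))
})

test_that("module recovery improves with the planted overlap fraction", {
  recover_frac <- function(overlap, s) {
    ds <- sim_ds(seed = s, n_probes = 400, groups = c(15, 15),
                 n_informative = 30, effect = 2)
    flt <- wilcoxon_filter(ds, 0.01)
    rks <- lapply(ds$sample_ids, function(id) rank_sample(ds, flt$retained, id))
    sigs <- lapply(rks, build_signature, n1 = 8, n2 = 8)
    bm <- extract_biomarker(sigs, ds$probe_to_gene, flt$pvalues)
    net <- simulate_network(net_sim_config(n_genes = 300,
                                           planted_module_size = 35,
                                           planted_overlap = overlap,
                                           seed = s),
                            attr(ds, "informative_genes"),
                            unique(unname(ds$probe_to_gene)))
    sc <- suppressWarnings(assign_node_scores(net, biomarker_gene_pvalues(bm)))
    et <- edge_scores(net, sc, 0.5)
    thr <- suppressWarnings(detect_threshold(et$score))
    sub <- extract_subnetwork(net, et, thr)
    mod <- attr(net, "module_genes")
    length(intersect(sub$genes, mod)) / length(union(sub$genes, mod))
  }
  jac <- vapply(c(0.2, 0.5, 0.8), function(ov)
    mean(vapply(1:10, function(s) recover_frac(ov, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(jac) > 0))
})
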