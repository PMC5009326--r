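test_that("complete 4v4 separation gives the exact rank-sum p of 2/70", {
  mat <- rbind(sep = c(1, 2, 3, 4, 5, 6, 7, 8),
               flat = rep(1, 8))
  ds <- manual_dataset(mat, rep(c("A", "B"), each = 4))
  flt <- wilcoxon_filter(ds, alpha_filter = 0.05)
  expect_equal(unname(flt$pvalues["sep"]), 2 / 70, tolerance = 1e-12)
  expect_equal(unname(flt$pvalues["flat"]), 1)
  expect_identical(flt$retained, "sep")
})

test_that("identical groups retain nothing; alpha 1 retains everything", {
  set.seed(1)
  half <- matrix(rnorm(40), nrow = 4)
  mat <- cbind(half, half)   # group B duplicates group A sample-for-sample
  ds <- manual_dataset(mat, rep(c("A", "B"), each = 10))
  flt <- wilcoxon_filter(ds, 0.05)
  expect_length(flt$retained, 0)
  all_in <- wilcoxon_filter(ds, 1)
  expect_setequal(all_in$retained, ds$probe_ids)
})

test_that("filter p-values agree with stats::wilcox.test with and without ties", {
  set.seed(7)
  mat <- matrix(sample(1:6, 15 * 60, replace = TRUE), nrow = 15)  # many ties
  mat <- rbind(mat, matrix(rnorm(5 * 60), nrow = 5))              # no ties
  ds <- manual_dataset(mat, rep(c("A", "B"), each = 30))
  flt <- wilcoxon_filter(ds, 1)
  g <- ds$group_labels
  ref <- vapply(seq_len(20), function(i)
    suppressWarnings(stats::wilcox.test(ds$abundance[i, g == "A"],
                                        ds$abundance[i, g == "B"],
                                        exact = FALSE)$p.value), numeric(1))
  expect_equal(unname(flt$pvalues), ref, tolerance = 1e-10)
})

test_that("single-group input errors", {
  mat <- matrix(rnorm(20), nrow = 2)
  expect_error(manual_dataset(mat, rep("A", 10)), "two distinct")
})

test_that("per-sample ranking is deterministic and probe-order invariant", {
  mat <- matrix(c(5, 4, 3, 2, 1,
                  2, 2, 2, 2, 2,
                  1, 2, 3, 4, 5,
                  3, 3, 2, 2, 1), ncol = 4,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  ds <- manual_dataset(mat, c("A", "A", "B", "B"))
  expect_identical(rank_sample(ds, paste0("p", 1:5), "s1"), paste0("p", 1:5))
  # all-equal sample falls back to lexicographic probe order
  expect_identical(rank_sample(ds, paste0("p", 1:5), "s2"), paste0("p", 1:5))
  # permuting the retained vector does not change the result
  set.seed(3)
  for (i in 1:50) {
    perm <- sample(paste0("p", 1:5))
    expect_identical(rank_sample(ds, perm, "s1"), paste0("p", 1:5))
  }
})

test_that("signatures take the first n1 and last n2 of the ranking", {
  ranked <- letters[1:6]
  sig <- build_signature(ranked, 2, 2)
  expect_identical(sig$top, c("a", "b"))
  expect_identical(sig$bottom, c("e", "f"))
  full <- build_signature(ranked, 3, 3)
  expect_setequal(c(full$top, full$bottom), ranked)
  two <- build_signature(letters[1:2], 1, 1)
  expect_identical(two$top, "a")
  expect_identical(two$bottom, "b")
  expect_error(build_signature(ranked, 4, 3), "exceeds")
})

test_that("biomarker is the union of signature probes with deduplicated genes", {
  p2g <- stats::setNames(c("g1", "g1", "g2", "g3"), c("a", "b", "c", "d"))
  pv <- stats::setNames(c(0.01, 0.02, 0.03, 0.04), c("a", "b", "c", "d"))
  shared <- list(structure(list(top = c("a", "b"), bottom = c("c", "d")),
                           class = "sample_signature"))
  bm <- extract_biomarker(rep(shared, 5), p2g, pv)
  expect_length(bm$probe_ids, 4)
  expect_setequal(bm$gene_symbols, c("g1", "g2", "g3"))
  sig2 <- list(structure(list(top = c("a", "b"), bottom = character(0)),
                         class = "sample_signature"),
               structure(list(top = c("c", "d"), bottom = character(0)),
                         class = "sample_signature"))
  bm2 <- extract_biomarker(sig2, p2g, pv)
  expect_length(bm2$probe_ids, 4)
  gp <- biomarker_gene_pvalues(bm)
  expect_equal(unname(gp["g1"]), 0.01)  # min over probes a, b
})
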