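test_that("hypergeometric p matches exact enumeration on small universes", {
  # closed case: all 5 query genes in a 5-gene set, universe 20
  universe <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(hit = universe[1:5]), universe)
  res <- ora(universe[1:5], coll, fdr_threshold = 0.01)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # random cases vs combinatorial enumeration
  set.seed(30)
  for (rep in 1:20) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    gs <- sample(uni, K)
    qu <- sample(uni, n)
    k <- length(intersect(gs, qu))
    # exact tail: sum over j >= k of C(K,j) C(N-K,n-j) / C(N,n)
    jmax <- min(K, n)
    exact <- sum(choose(K, k:jmax) * choose(N - K, n - (k:jmax))) / choose(N, n)
    res <- ora(qu, gene_set_collection(list(s = gs), uni))
    expect_equal(res$p, exact, tolerance = 1e-12)
  }
})

test_that("zero overlap gives p = 1 and saturation gives p = 1 for every set", {
  uni <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(a = uni[1:5], b = uni[6:10]), uni)
  res <- ora(uni[11:15], coll)
  expect_equal(res$p[res$set == "a"], 1)
  sat <- ora(uni, coll)
  expect_true(all(sat$p == 1))
  expect_true(all(sat$k == sat$K))
})

test_that("query genes outside the universe are dropped with a warning", {
  uni <- sprintf("g%02d", 1:10)
  coll <- gene_set_collection(list(a = uni[1:4]), uni)
  expect_warning(res <- ora(c(uni[1:3], "NOT_A_GENE"), coll), "dropped")
  expect_equal(res$n, 3)
  expect_error(suppressWarnings(ora("NOT_A_GENE", coll)), "universe")
})

test_that("BH q-values are monotone in p-rank and never below p", {
  set.seed(9)
  uni <- sprintf("g%03d", 1:200)
  sets <- lapply(1:30, function(i) sample(uni, 20))
  names(sets) <- sprintf("S%02d", 1:30)
  coll <- gene_set_collection(sets, uni)
  res <- ora(sample(uni, 40), coll)
  expect_true(all(diff(res$q) >= -1e-12))   # sorted by p => q nondecreasing
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("de_filter applies the joint fold-change and p-value rule", {
  set.seed(2)
  nA <- 6; nB <- 6
  base <- matrix(rnorm(3 * (nA + nB), mean = 100, sd = 3), nrow = 3)
  rownames(base) <- c("up", "weak", "flat")
  A <- base[, 1:nA]; B <- base[, (nA + 1):(nA + nB)]
  A["up", ] <- B["up", ] * 1.6 + rnorm(nA, sd = 0.5)     # FC ~1.6, tiny p
  A["weak", ] <- B["weak", ] * 1.25 + rnorm(nA, sd = 0.2) # FC ~1.25 < 1.5
  res <- de_filter(A, B, fc_threshold = 1.5, p_threshold = 0.02)
  expect_true(res$pass[res$gene == "up"])
  expect_false(res$pass[res$gene == "weak"])   # p small but FC below 1.5
  expect_lt(res$p[res$gene == "weak"], 0.02)
  expect_false(res$pass[res$gene == "flat"])

  ident <- matrix(rep(c(4, 5), each = 4), nrow = 2, byrow = TRUE,
                  dimnames = list(c("x", "y"), NULL))
  resi <- de_filter(ident, ident)
  expect_equal(resi$fold_change, c(1, 1))
  expect_equal(resi$p, c(1, 1))
  expect_false(any(resi$pass))
  expect_error(de_filter(A[, 1, drop = FALSE], B), ">= 2")
})
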