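test_that("classify picks the closest group and flags exact ties", {
  d <- c(s1 = 0, s2 = 0.9, s3 = 0.8)
  lab <- classify(d, c("X", "Y", "Y"))
  expect_equal(as.character(lab), "X")
  expect_false(attr(lab, "tie"))
  tied <- classify(c(a = 0.5, b = 0.5), c("B", "A"))
  expect_equal(as.character(tied), "A")   # lexicographic tie-break
  expect_true(attr(tied, "tie"))
})

test_that("self-classification is perfect on strongly separable data", {
  for (s in 1:5) {
    ds <- sim_ds(seed = s, n_probes = 200, groups = c(10, 10),
                 n_informative = 30, effect = 3)
    flt <- wilcoxon_filter(ds, 0.05)
    dm <- distance_matrix(ds, flt$retained, 8, 8)
    pred <- vapply(seq_len(nrow(dm$D)), function(i)
      as.character(classify(dm$D[i, -i], ds$group_labels[-i])), character(1))
    expect_equal(mean(pred == ds$group_labels), 1.0)
  }
})

test_that("cross-validation folds partition all samples and CV has no leakage", {
  ds <- sim_ds(seed = 2, n_probes = 150, groups = c(12, 12),
               n_informative = 20, effect = 2)
  cv <- cross_validate(ds, classifier_params(5, 5, 0.05), n_folds = 4,
                       seed = 9)
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_length(cv$folds, 24)
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))

  # label-permuted data: accuracy should hover near the majority-class rate
  null_acc <- vapply(1:20, function(s) {
    perm <- ds
    set.seed(100 + s)
    perm$group_labels[] <- sample(as.character(ds$group_labels))
    cv0 <- suppressWarnings(cross_validate(perm, classifier_params(5, 5, 0.5),
                                           n_folds = 4, seed = s))
    cv0$mean_accuracy
  }, numeric(1))
  maj <- 0.5
  se <- stats::sd(null_acc) / sqrt(length(null_acc))
  expect_lt(abs(mean(null_acc) - maj), 3 * se + 0.05)
})

test_that("separable data cross-validates accurately and folds shrink with warning", {
  ds <- sim_ds(seed = 4, n_probes = 200, groups = c(12, 10),
               n_informative = 25, effect = 2)
  cv <- cross_validate(ds, classifier_params(8, 8, 0.05), n_folds = 5,
                       seed = 3)
  expect_gte(cv$mean_accuracy, 0.9)
  expect_warning(cross_validate(ds, classifier_params(3, 3, 0.05),
                                n_folds = 20, seed = 1), "folds")
})

test_that("permutation p-value is calibrated at its extremes", {
  ds <- sim_ds(seed = 6, n_probes = 150, groups = c(10, 10),
               n_informative = 25, effect = 3)
  pt <- permutation_test(ds, classifier_params(5, 5, 0.05), n_perm = 99,
                         seed = 2)
  # separable data: observed accuracy beats every permutation
  expect_equal(pt$p, 1 / 100)
  expect_true(pt$p > 0 && pt$p <= 1)
  expect_equal(pt$observed, 1.0)
})

test_that("probe-unit permutation destroys class structure", {
  ds <- sim_ds(seed = 8, n_probes = 60, groups = c(6, 6), n_informative = 15,
               effect = 3)
  pt <- permutation_test(ds, classifier_params(4, 4, 0.5), n_perm = 19,
                         unit = "probe", seed = 4)
  expect_equal(pt$unit, "probe")
  # permuted accuracies sit below the observed separation (they retain some
  # optimism because the probe filter is refit on each permuted dataset)
  expect_equal(pt$observed, 1.0)
  expect_lt(mean(pt$permuted), pt$observed)
  expect_lte(pt$p, 0.3)
  expect_gt(pt$p, 0)
})

test_that("stronger planted effects never degrade mean CV accuracy", {
  mean_acc <- vapply(c(0.5, 1, 2), function(es) {
    mean(vapply(1:10, function(s) {
      ds <- sim_ds(seed = s, n_probes = 150, groups = c(12, 12),
                   n_informative = 20, effect = es)
      suppressWarnings(cross_validate(ds, classifier_params(5, 5, 0.05),
                                      n_folds = 4, seed = s))$mean_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= -0.02))
  expect_gt(mean_acc[3], mean_acc[1])
})
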