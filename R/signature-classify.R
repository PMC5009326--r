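#' Classifier parameter set
#'
#' @param n1 number of top probes per signature (same for every sample).
#' @param n2 number of bottom probes per signature.
#' @param alpha_filter Wilcoxon filter stringency in `(0, 1]`.
#' @param weight_exponent weighting exponent of the enrichment-score distance.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(n1 = 10L, n2 = 10L, alpha_filter = 0.01,
                              weight_exponent = 1) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L) stop("n1 and n2 must be >= 1", call. = FALSE)
  if (alpha_filter <= 0 || alpha_filter > 1)
    stop("alpha_filter must be in (0, 1]", call. = FALSE)
  if (weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, alpha_filter = alpha_filter,
                 weight_exponent = weight_exponent),
            class = "classifier_params")
}

#' Nearest-group classification of one sample
#'
#' Assigns the sample to the group whose training members have the lowest
#' mean distance from it. An exact tie goes to the lexicographically smaller
#' label and is flagged in attribute `tie`.
#'
#' @param dist_to_train named numeric vector of distances from the sample to
#'   each training sample.
#' @param train_labels group labels of the training samples (same order).
#' @return The predicted label (character scalar) with attribute `tie`.
#' @export
classify <- function(dist_to_train, train_labels) {
  train_labels <- as.character(train_labels)
  means <- tapply(dist_to_train, train_labels, mean)
  means <- means[sort(names(means))]
  tie <- length(means) > 1L && diff(range(means)) == 0
  lab <- names(means)[which.min(means)]
  attr(lab, "tie") <- tie
  lab
}

# Leave-one-out nearest-group prediction from a full distance matrix.
loo_predict <- function(D, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  inA <- labels == lv[1L]
  sumA <- D %*% inA
  sumB <- D %*% (!inA)
  # zero diagonal: leaving sample i out only shrinks its own group's count
  meanA <- sumA / (sum(inA) - inA)
  meanB <- sumB / (sum(!inA) - !inA)
  ifelse(meanA <= meanB, lv[1L], lv[2L])
}

classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- mean(truth == pred)
  tp <- sum(pred == positive & truth == positive)
  prec <- if (sum(pred == positive) > 0) tp / sum(pred == positive) else NA_real_
  rec <- if (sum(truth == positive) > 0) tp / sum(truth == positive) else NA_real_
  c(accuracy = acc, precision = prec, recall = rec)
}

# Stratified fold assignment; returns integer vector of fold ids per sample.
stratified_folds <- function(labels, n_folds) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified cross-validation of the rank-signature classifier
#'
#' Probe filtering and signature construction are re-fit inside each training
#' fold only, so no information leaks from test samples into feature
#' selection. Folds are stratified by group; when the smaller group has fewer
#' members than `n_folds` the fold count is reduced with a warning. When a
#' training fold retains fewer than `n1 + n2` probes the signature lengths are
#' shrunk proportionally for that fold (with a warning).
#'
#' @param ds an [expression_dataset()].
#' @param params a [classifier_params()].
#' @param n_folds number of folds; default 10.
#' @param seed integer seed for the fold assignment.
#' @return A `cv_report`: list with `folds` (per-sample fold id), `per_fold`
#'   data frame of accuracy/precision/recall, the fold-mean and SD of each
#'   metric, `predictions` and `params`. The positive class for
#'   precision/recall is the alphabetically second group label.
#' @export
cross_validate <- function(ds, params, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(params, "classifier_params"))
  labels <- ds$group_labels
  min_group <- min(table(labels))
  if (min_group < n_folds) {
    n_folds <- max(2L, as.integer(min_group))
    warning("group smaller than requested folds; using ", n_folds, " folds",
            call. = FALSE)
  }
  fold <- withr_seed(seed, stratified_folds(labels, n_folds))
  positive <- sort(unique(as.character(labels)))[2L]
  pred <- character(length(labels))

  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    train_ds <- subset_samples(ds, train_idx)
    flt <- wilcoxon_filter(train_ds, params$alpha_filter)
    retained <- flt$retained
    if (length(retained) < 2L) {
      # degenerate fold: fall back to all probes so prediction is defined
      retained <- sort(ds$probe_ids)
    }
    n1 <- params$n1; n2 <- params$n2
    if (n1 + n2 > length(retained)) {
      scl <- length(retained) / (n1 + n2)
      n1 <- max(1L, floor(n1 * scl)); n2 <- max(1L, floor(n2 * scl))
      if (n1 + n2 > length(retained)) n2 <- length(retained) - n1
      warning("signature length reduced to fit ", length(retained),
              " retained probes", call. = FALSE)
    }
    Dx <- cross_distances_kernel(ds$abundance[retained, , drop = FALSE],
                                 n1, n2, test_idx, train_idx,
                                 params$weight_exponent)
    for (a in seq_along(test_idx))
      pred[test_idx[a]] <- classify(Dx[a, ], labels[train_idx])
  }

  per_fold <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    idx <- which(fold == f)
    as.data.frame(t(classification_metrics(labels[idx], pred[idx], positive)))
  }))
  per_fold$fold <- seq_len(n_folds)
  structure(list(folds = fold,
                 per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 sd_accuracy = stats::sd(per_fold$accuracy),
                 mean_precision = mean(per_fold$precision, na.rm = TRUE),
                 mean_recall = mean(per_fold$recall, na.rm = TRUE),
                 predictions = stats::setNames(pred, ds$sample_ids),
                 positive_class = positive,
                 params = params),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: accuracy %.3f (sd %.3f), precision %.3f, recall %.3f over %d folds\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_precision, x$mean_recall,
              nrow(x$per_fold)))
  invisible(x)
}

# Restrict an expression dataset to a subset of sample indices.
subset_samples <- function(ds, idx) {
  expression_dataset(ds$abundance[, idx, drop = FALSE],
                     ds$group_labels[idx], ds$probe_to_gene)
}

#' Permutation test of classification performance
#'
#' Compares the observed leave-one-out classification accuracy against an
#' empirical null distribution, re-running the full procedure — probe
#' filtering, signature construction and distance computation — on every
#' permuted dataset so that the selection step cannot bias the test. Two
#' permutation units are available: `"sample"` permutes the group labels
#' (default; sample ranks are label-free and reused, making this fast), and
#' `"probe"` independently permutes each sample's values across probes
#' (expensive; use a small `n_perm`).
#'
#' @param ds an [expression_dataset()].
#' @param params a [classifier_params()].
#' @param n_perm number of permutations; default 10000 for the sample unit.
#' @param unit `"sample"` or `"probe"`.
#' @param seed integer seed.
#' @return List with `p` (the add-one empirical p-value
#'   `(1 + #\{perm >= obs\}) / (1 + n_perm)`), `observed` accuracy and the
#'   vector of permuted accuracies.
#' @export
permutation_test <- function(ds, params, n_perm = 10000L,
                             unit = c("sample", "probe"), seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(inherits(params, "classifier_params"))
  labels <- as.character(ds$group_labels)
  lv <- sort(unique(labels))
  mat <- ds$abundance
  ids <- sort(rownames(mat))

  # full-procedure statistic for a label assignment: filter, signatures,
  # distances, leave-one-out accuracy. The leave-one-out group-separation
  # margin (bounded in [-1, 1]) breaks the heavy ties of the discrete
  # accuracy, keeping the permutation p-value near-uniform under the null;
  # its weight is far below the accuracy granularity 1/n.
  stat_for <- function(pre, m, labs) {
    p <- ranksum_pvalues(pre, which(labs == lv[1L]))
    retained <- sort(rownames(m)[p <= params$alpha_filter])
    if (length(retained) < params$n1 + params$n2) retained <- ids
    rp <- rank_positions(m[retained, , drop = FALSE])
    D <- kernel_distances(rp, params$n1, params$n2, params$weight_exponent)
    inA <- labs == lv[1L]
    meanA <- (D %*% inA) / (sum(inA) - inA)
    meanB <- (D %*% !inA) / (sum(!inA) - !inA)
    pred <- ifelse(meanA <= meanB, lv[1L], lv[2L])
    margin <- mean(ifelse(inA, meanB - meanA, meanA - meanB))
    c(acc = mean(pred == labs), stat = mean(pred == labs) + margin * 1e-4)
  }

  pre0 <- precompute_ranksum(mat)
  obs <- stat_for(pre0, mat, labels)

  perm_stat <- withr_seed(seed, {
    if (unit == "sample") {
      vapply(seq_len(n_perm), function(b)
        stat_for(pre0, mat, sample(labels)), numeric(2))
    } else {
      vapply(seq_len(n_perm), function(b) {
        shuf <- apply(mat, 2L, sample)
        rownames(shuf) <- rownames(mat)
        stat_for(precompute_ranksum(shuf), shuf, labels)
      }, numeric(2))
    }
  })
  p <- (1 + sum(perm_stat["stat", ] >= obs["stat"])) / (1 + n_perm)
  list(p = p, observed = unname(obs["acc"]),
       permuted = unname(perm_stat["acc", ]), unit = unit)
}
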