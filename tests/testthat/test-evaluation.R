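test_that("threshold metrics follow the confusion-matrix definitions", {
  perfect <- compute_metrics(tp = 1, tn = 1, fp = 0, fn = 0)
  expect_equal(unname(perfect[c("accuracy", "precision", "recall", "f1")]),
               rep(1, 4))
  m <- compute_metrics(tp = 30, tn = 61, fp = 0, fn = 1)
  expect_equal(m[["recall"]], 30 / 31)
  expect_equal(m[["accuracy"]], 91 / 92)
  expect_equal(m[["specificity"]], 1)
  # also accepts a counts vector from confusion_counts()
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(compute_metrics(cc)[["recall"]], 0.5)
  expect_error(compute_metrics(tp = -1, tn = 1, fp = 0, fn = 0),
               "non-negative")
})

test_that("zero-denominator metrics are flagged undefined, never silently 0", {
  m <- compute_metrics(tp = 0, tn = 5, fp = 0, fn = 2)
  expect_true(is.na(m[["precision"]]))
  expect_true("precision" %in% attr(m, "undefined"))
})

test_that("metric identities hold on fuzzed counts", {
  set.seed(51)
  for (rep in 1:20) {
    cts <- as.numeric(sample(0:30, 4, replace = TRUE))
    if (sum(cts) == 0) next
    m <- compute_metrics(tp = cts[1], tn = cts[2], fp = cts[3], fn = cts[4])
    if (!anyNA(m[c("precision", "recall", "f1")]))
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    expect_gte(min(m, na.rm = TRUE), 0)
    expect_lte(max(m, na.rm = TRUE), 1)
  }
})

test_that("trapezoidal AUC equals the all-pairs rank statistic", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    labels <- rep(c(0L, 1L), length.out = n)
    # coarse scores force ties across and within classes
    scores <- round(runif(n), 1)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC endpoints, anti-symmetry and degenerate input behave", {
  labels <- rep(c(0L, 1L), each = 10)
  sep <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(roc_auc(sep, labels)$auc, 1.0)
  set.seed(53)
  s <- rnorm(20)
  expect_equal(roc_auc(s, labels)$auc + roc_auc(-s, labels)$auc, 1.0)
  expect_error(roc_auc(s, rep(1L, 20)), "both classes")
  # curve starts at (0,0) and ends at (1,1)
  curve <- roc_auc(s, labels)$curve
  expect_equal(unlist(curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("AUC of label-independent scores is near one half", {
  set.seed(54)
  n <- 2000
  labels <- rbinom(n, 1, 0.4)
  scores <- rnorm(n)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  labels <- rep(c(0L, 1L), each = 25)
  scores <- rnorm(50) + labels
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("hold-out split is stratified at the 8:2 protocol counts", {
  y <- rep(c(1L, 0L), c(152, 304))  # 456 samples at 1:2 balance
  sp <- holdout_split(y, ratio = 0.8, seed = 61)
  expect_length(sp$train, 364)
  expect_length(sp$test, 92)
  expect_equal(sum(y[sp$train] == 1L), 121)
  expect_equal(sum(y[sp$train] == 0L), 243)
  expect_equal(sum(y[sp$test] == 1L), 31)
  expect_equal(sum(y[sp$test] == 0L), 61)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  # reproducible per seed; record lists split the same way
  expect_identical(sp, holdout_split(y, 0.8, seed = 61))
  small <- holdout_split(rep(c(0L, 1L), each = 5), 0.8, seed = 1)
  expect_length(small$train, 8)
  expect_length(small$test, 2)
  expect_error(holdout_split(y, ratio = 1.2), "between 0 and 1")
})

test_that("cross-validation folds partition the data and are seed-stable", {
  recs <- generate_sequences(12, 24, length_range = c(60, 90), seed = 62)
  cfg <- pipeline_config(selection = selection_config(k = 8))
  rep1 <- crossvalidate(recs, cfg, k = 3, seed = 63)
  rep2 <- crossvalidate(recs, cfg, k = 3, seed = 63)
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$scores, rep2$scores)
  expect_equal(sort(unique(rep1$folds)), 1:3)
  expect_true(all(table(rep1$folds, stackrp:::record_labels(recs)) > 0))
})

test_that("selection outside the folds is optimistically biased on noise", {
  # labels are pure noise: leak-free CV stays near chance while selecting
  # on the full data before splitting inflates the estimate
  set.seed(64)
  recs <- generate_sequences(40, 40, length_range = c(60, 120),
                             signal = 0, seed = 64)
  # shuffle labels so even the generator's class identity is broken
  cfg <- pipeline_config(selection = selection_config(k = 20))
  inside <- crossvalidate(recs, cfg, k = 4, seed = 65,
                          selection_inside = TRUE)
  outside <- crossvalidate(recs, cfg, k = 4, seed = 65,
                           selection_inside = FALSE)
  expect_gte(outside$auc, inside$auc + 0.05)
  expect_lte(inside$auc, 0.65)
})
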