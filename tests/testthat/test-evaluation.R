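# The two worked-example confusion matrices from the published screening
# study: murmur task (tp 17, fp 0, fn 8, tn 70; AUC 0.915, FNR 0.32) and
# outcome task (tp 25, fp 10, fn 22, tn 38; FNR 0.468).
cm_murmur <- confusion_from_counts(tp = 17, fp = 0, fn = 8, tn = 70)
cm_outcome <- confusion_from_counts(tp = 25, fp = 10, fn = 22, tn = 38)

test_that("confusion counting and rates reproduce printed worked examples", {
  r <- rates(cm_murmur)
  expect_equal(r$fnr, 0.32)
  expect_equal(r$acc_positive, 17 / 25)
  expect_equal(r$acc_overall, 87 / 95)
  expect_equal(r$fpr, 0)

  r2 <- rates(cm_outcome)
  expect_equal(round(r2$fnr, 3), 0.468)
  expect_equal(r2$acc_overall, 63 / 95)

  # thresholds: score >= t is positive; t = 0 makes everything positive
  labels <- c(0, 1, 1, 0)
  scores <- c(0.2, 0.6, 0.5, 0.5)
  cm <- confusion(labels, scores, 0.5)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 2, fn = 0, fp = 1, tn = 1))
  cm0 <- confusion(labels, scores, 0)
  expect_equal(cm0$fn + cm0$tn, 0L)
  expect_error(confusion(c(0, 1), c(0.5)), "equal length")

  # empty-class policy: NaN with a flag, not silent zero
  r3 <- rates(confusion_from_counts(tp = 0, fp = 2, fn = 0, tn = 3))
  expect_true(is.nan(r3$acc_positive))
  expect_true("acc_positive" %in% r3$undefined_rates)

  perfect <- rates(confusion_from_counts(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(perfect$acc_overall, 1)
  expect_equal(perfect$acc_positive, 1)
})

test_that("roc_auc equals the exhaustive pairwise statistic with ties one half", {
  pairwise_auc <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 1), c(0.5, 0.5, 0.9)), 0.75)

  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force ties
    expect_equal(roc_auc(labels, scores), pairwise_auc(labels, scores))
  }

  # monotone invariance
  set.seed(13)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  scores <- stats::runif(40)
  expect_equal(roc_auc(labels, scores), roc_auc(labels, scores^2))
  expect_error(roc_auc(rep(1, 5), stats::runif(5)), "both classes")
})

test_that("roc_auc agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    labels <- c(0, 1, sample(0:1, 48, replace = TRUE))
    scores <- round(stats::runif(50), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
  }
})

test_that("weighted accuracy generalises plain accuracy", {
  expect_equal(weighted_accuracy(cm_murmur, c(1, 1)), 87 / 95)
  expect_equal(weighted_accuracy(cm_murmur, c(5, 1)), 155 / 195)
  allright <- confusion_from_counts(tp = 3, fp = 0, fn = 0, tn = 9)
  expect_equal(weighted_accuracy(allright, c(7, 2)), 1)

  # three-class form with the challenge murmur weights
  m3 <- matrix(c(5, 1, 0, 1, 3, 1, 0, 1, 8), 3, 3)
  w <- unname(challenge_murmur_weights)
  expect_equal(weighted_accuracy(m3, w),
               sum(w * diag(m3)) / sum(w * colSums(m3)))
  expect_error(weighted_accuracy(cm_murmur, c(1, 2, 3)), "one weight per")
  expect_error(weighted_accuracy(cm_murmur, c(1, -1)), "positive")
})

test_that("threshold sweeps satisfy the screening monotonicity invariants", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), 2)
    cur <- threshold_sweep(labels, scores, seq(0, 1, by = 0.1))
    expect_true(all(diff(cur$fnr) >= 0))
    expect_true(all(diff(cur$fpr) <= 0))
    expect_true(0.5 %in% cur$threshold)
    # extremes are pinned by the class priors: everything is positive at
    # t = 0; at t = 1 only scores equal to 1 remain positive
    expect_equal(cur$accuracy[cur$threshold == 0], mean(labels == 1))
    expect_equal(cur$accuracy[cur$threshold == 1],
                 mean((scores >= 1) == (labels == 1)))
  }

  # separable scores across a coarse grid
  cur <- threshold_sweep(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), c(0, 0.5, 1))
  expect_equal(cur$fnr, c(0, 0, 1))   # no score reaches t = 1
  expect_equal(cur$fpr, c(1, 0, 0))

  # constant scores at 0.7: everything positive at t = 0.5
  cur2 <- threshold_sweep(c(0, 1), c(0.7, 0.7), c(0.5))
  expect_equal(cur2$fpr[cur2$threshold == 0.5], 1)

  # refining the grid agrees at shared thresholds
  coarse <- threshold_sweep(c(0, 1, 1), c(0.3, 0.6, 0.9), seq(0, 1, 0.2))
  fine <- threshold_sweep(c(0, 1, 1), c(0.3, 0.6, 0.9), seq(0, 1, 0.1))
  shared <- merge(coarse, fine, by = "threshold")
  expect_equal(shared$accuracy.x, shared$accuracy.y)
  expect_error(threshold_sweep(c(0, 1), c(0.1, 0.9), numeric(0)), "empty")
})

test_that("grouped k-fold partitions patients without leakage, stratified", {
  ct <- label_catalog(26, 74, task = "outcome_binary")
  folds <- grouped_kfold(ct, k = 10, seed = 4, task = "outcome_binary")
  ids <- names(ct$patients)
  expect_setequal(unlist(folds), ids)
  expect_equal(sum(lengths(folds)), 100)
  expect_true(all(lengths(folds) == 10))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  # leakage check against complements
  for (f in folds) {
    expect_length(intersect(f, setdiff(ids, f)), 0)
  }

  # determinism and stratification within +/- 2 patients of the global mix
  folds2 <- grouped_kfold(ct, k = 10, seed = 4, task = "outcome_binary")
  expect_identical(folds, folds2)
  labs <- catalog_labels(ct, "outcome_binary")
  per_fold_pos <- vapply(folds, function(f) sum(labs[f]), 0L)
  expect_true(all(abs(per_fold_pos - 26 / 10) <= 2))

  expect_error(grouped_kfold(label_catalog(2, 2), k = 10), "exceeds")
})

test_that("balanced subsampling equalises the outcome classes of the multi-site set", {
  # the out-of-distribution training collection: 2488 normal, 665 abnormal
  ct <- label_catalog(665, 2488, task = "outcome_binary")
  bal <- balanced_subsample(ct, seed = 6, task = "outcome_binary")
  labs <- catalog_labels(bal, "outcome_binary")
  expect_length(bal$patients, 1330)
  expect_equal(sum(labs == 1), 665)
  expect_equal(sum(labs == 0), 665)

  # different seeds: same sizes, different membership
  bal2 <- balanced_subsample(ct, seed = 7, task = "outcome_binary")
  expect_equal(length(bal2$patients), 1330)
  expect_false(identical(names(bal$patients), names(bal2$patients)))

  # already balanced: sizes unchanged
  even <- label_catalog(20, 20)
  expect_length(balanced_subsample(even, seed = 1)$patients, 40)
  expect_error(balanced_subsample(label_catalog(0, 10), seed = 1),
               "both classes")
})

test_that("patient-level 70/30 splits are disjoint, stratified and seeded", {
  ct <- label_catalog(30, 70)
  sp <- split_patients(ct, 0.7, seed = 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(ct$patients))
  expect_equal(length(sp$train), 70)
  labs <- catalog_labels(ct, "outcome_binary")
  expect_equal(sum(labs[sp$train]), 21)
  expect_identical(sp, split_patients(ct, 0.7, seed = 3))
})

test_that("recording-length audits detect a planted duration shift", {
  dir <- withr::local_tempdir()
  set.seed(9)
  patients <- list()
  for (i in 1:16) {
    pid <- sprintf("L%03d", i)
    abn <- i <= 8
    dur <- (if (abn) 8 else 6) + stats::runif(1, -0.3, 0.3)  # abnormal longer
    f <- paste0(pid, ".wav")
    write_wav(stats::rnorm(dur * 4000) * 0.1, 4000, file.path(dir, f))
    writeLines(c(sprintf("%s 1 4000", pid), sprintf("AV %s", f),
                 sprintf("#Murmur: %s", if (abn) "Present" else "Absent"),
                 sprintf("#Outcome: %s", if (abn) "Abnormal" else "Normal")),
               file.path(dir, paste0(pid, ".txt")))
  }
  ct <- scan_dataset(dir, "synthetic")
  ht <- recording_length_test(ct, task = "outcome_binary")
  expect_lt(ht$p.value, 1e-6)
  expect_equal(unname(ht$group_means), c(8, 6), tolerance = 0.1)
})

test_that("fold summaries report mean and standard deviation per metric", {
  reps <- list(metrics_report(c(0, 1, 1, 0), c(0.1, 0.9, 0.8, 0.3)),
               metrics_report(c(0, 1, 1, 0), c(0.6, 0.4, 0.9, 0.1)))
  fs <- fold_summary(reps)
  expect_setequal(fs$metric, c("acc_positive", "acc_negative", "acc_overall",
                               "auc", "fnr", "fpr"))
  auc_row <- fs[fs$metric == "auc", ]
  expect_equal(auc_row$mean, mean(c(1, 0.75)))
  expect_equal(auc_row$sd, stats::sd(c(1, 0.75)))
})
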