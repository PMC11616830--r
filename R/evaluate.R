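# Metrics, threshold analysis, patient-grouped cross-validation, balanced
# subsampling and zero-shot transfer evaluation.

#' Binary confusion matrix at a threshold
#'
#' Tie policy: a score equal to the threshold counts as positive
#' (`score >= threshold`).
#'
#' @param labels Binary 0/1 vector.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `confusion2` with integer `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  stopifnot(all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1 & labels == 1),
                 fn = sum(pred == 0 & labels == 1),
                 fp = sum(pred == 1 & labels == 0),
                 tn = sum(pred == 0 & labels == 0)),
            class = "confusion2")
}

#' Build a confusion matrix from its four cells
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `confusion2` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion2")
}

#' @export
print.confusion2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("pred+", "pred-"), c("true+", "true-")))
  print(m)
  invisible(x)
}

#' Classification rates from a confusion matrix
#'
#' `acc_overall = (tp+tn)/n`; `acc_positive = tp/(tp+fn)` (sensitivity, the
#' "Acc. Present/Unknown" / "Acc. Abnormal" column); `acc_negative =
#' tn/(tn+fp)` (specificity); `fnr`, `fpr` their complements. A rate whose
#' class is empty is reported as `NaN` with the `undefined_rates` field
#' naming it, never silently as 0.
#'
#' @param cm A `confusion2`.
#' @return List: `acc_overall`, `acc_positive`, `acc_negative`, `fnr`,
#'   `fpr`, `n`, `undefined_rates`.
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "confusion2"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix")
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  undef <- character()
  if (pos == 0) undef <- c(undef, "acc_positive", "fnr")
  if (neg == 0) undef <- c(undef, "acc_negative", "fpr")
  list(acc_overall = (cm$tp + cm$tn) / n,
       acc_positive = if (pos > 0) cm$tp / pos else NaN,
       acc_negative = if (neg > 0) cm$tn / neg else NaN,
       fnr = if (pos > 0) cm$fn / pos else NaN,
       fpr = if (neg > 0) cm$fp / neg else NaN,
       n = n, undefined_rates = undef)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: equals the fraction of
#' (positive, negative) pairs ranked correctly, ties counting one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param labels Binary 0/1 vector containing both classes.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted accuracy
#'
#' `sum_i w_i correct_i / sum_i w_i total_i` over true classes `i`; reduces
#' to plain accuracy under equal weights. Accepts a `confusion2` (classes
#' ordered positive, negative) or a square multi-class confusion matrix with
#' true classes in columns and predicted classes in rows (the convention of
#' the three-class murmur scoring, whose challenge weights 5/3/1 ship as
#' [challenge_murmur_weights]).
#'
#' @param cm A `confusion2` or square numeric matrix.
#' @param weights Positive weight per true class.
#' @return Weighted accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(cm, weights) {
  if (inherits(cm, "confusion2")) {
    cm <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2)
  }
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (length(weights) != ncol(cm))
    stop("need one weight per class (", ncol(cm), "), got ", length(weights))
  if (any(weights <= 0)) stop("weights must be positive")
  sum(weights * diag(cm)) / sum(weights * colSums(cm))
}

#' Murmur-class weights of the 2022 challenge scoring
#'
#' Weight 5 for Present, 3 for Unknown, 1 for Absent, as defined by the
#' challenge organisers (not re-derived here).
#' @export
challenge_murmur_weights <- c(Present = 5, Unknown = 3, Absent = 1)

#' Accuracy/FPR/FNR across a grid of decision thresholds
#'
#' @param labels Binary 0/1 vector.
#' @param scores Scores in `[0, 1]`.
#' @param grid Thresholds in `[0, 1]`; 0.5 is always included.
#' @return Data frame of class `threshold_curve`: `threshold`, `accuracy`,
#'   `fpr`, `fnr`.
#' @export
threshold_sweep <- function(labels, scores,
                            grid = seq(0, 1, by = 0.05)) {
  if (length(grid) == 0) stop("empty threshold grid")
  if (any(grid < 0 | grid > 1)) stop("thresholds must lie in [0, 1]")
  grid <- sort(unique(c(grid, 0.5)))
  rows <- lapply(grid, function(t) {
    r <- rates(confusion(labels, scores, t))
    data.frame(threshold = t, accuracy = r$acc_overall,
               fpr = r$fpr, fnr = r$fnr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' Patient-grouped, label-stratified k-fold assignment
#'
#' Folds partition patients (never windows or recordings), so no subject's
#' data can span train and test. Within each label stratum patients are
#' shuffled by the seed and dealt round-robin, keeping per-fold label
#' proportions within one patient of the global mix.
#'
#' @param catalog A `dataset_catalog`.
#' @param k Number of folds (default 10).
#' @param seed RNG seed.
#' @param task Label used for stratification.
#' @return List of k character vectors of patient ids.
#' @export
grouped_kfold <- function(catalog, k = 10, seed = 1L,
                          task = "murmur_binary") {
  ids <- names(catalog$patients)
  if (k > length(ids)) stop("k exceeds the number of patients")
  labels <- catalog_labels(catalog, task)
  labels[is.na(labels)] <- -1L
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (g in split(ids, labels[ids])) {
    g <- sample(g)
    for (i in seq_along(g)) {
      f <- ((i - 1L + offset) %% k) + 1L
      folds[[f]] <- c(folds[[f]], g[i])
    }
    offset <- offset + length(g)
  }
  lapply(folds, sort)
}

#' Seeded patient-level train/test split
#'
#' @param catalog A `dataset_catalog`.
#' @param train_fraction Fraction of patients assigned to training
#'   (default 0.7, the fine-tuning convention).
#' @param seed RNG seed.
#' @param task Stratification label.
#' @return List with character vectors `train` and `test`.
#' @export
split_patients <- function(catalog, train_fraction = 0.7, seed = 1L,
                           task = "outcome_binary") {
  ids <- names(catalog$patients)
  labels <- catalog_labels(catalog, task)
  labels[is.na(labels)] <- -1L
  set.seed(seed)
  train <- unlist(lapply(split(ids, labels[ids]), function(g) {
    sample(g, round(length(g) * train_fraction))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

#' Balanced subsample of a catalog
#'
#' Downsamples the majority class (without replacement) to the minority
#' count, so both classes are equally represented; deterministic per seed.
#'
#' @param catalog A `dataset_catalog`.
#' @param seed RNG seed.
#' @param task Label defining the classes.
#' @return A `dataset_catalog` with equal class counts.
#' @export
balanced_subsample <- function(catalog, seed = 1L, task = "outcome_binary") {
  labels <- catalog_labels(catalog, task)
  labels <- labels[!is.na(labels)]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("balanced_subsample requires both classes")
  m <- min(n1, n0)
  set.seed(seed)
  keep <- c(sample(names(labels)[labels == 1], m),
            sample(names(labels)[labels == 0], m))
  catalog_subset(catalog, keep)
}

#' Metrics report for one evaluated split
#'
#' @param labels Binary 0/1 vector.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `metrics_report`: the [rates()] fields plus `auc`
#'   and the confusion matrix.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion(labels, scores, threshold)
  r <- rates(cm)
  r$auc <- if (length(unique(labels)) == 2) roc_auc(labels, scores) else NaN
  r$threshold <- threshold
  r$confusion <- cm
  class(r) <- "metrics_report"
  r
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics n=%d> overall %.4f | positive %.4f | negative %.4f | AUC %.4f | FNR %.3f FPR %.3f (thr %.2f)\n",
    x$n, x$acc_overall, x$acc_positive, x$acc_negative, x$auc, x$fnr,
    x$fpr, x$threshold))
  invisible(x)
}

#' Mean and standard deviation across fold reports
#'
#' @param reports List of `metrics_report`s (one per fold).
#' @return Data frame with one row per metric: `mean` and `sd` across folds,
#'   the convention used for cross-validated result tables.
#' @export
fold_summary <- function(reports) {
  fields <- c("acc_positive", "acc_negative", "acc_overall", "auc",
              "fnr", "fpr")
  vals <- sapply(fields, function(f)
    vapply(reports, function(r) r[[f]], numeric(1)))
  data.frame(metric = fields,
             mean = apply(vals, 2, mean, na.rm = TRUE),
             sd = apply(vals, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' Two-sample comparison of recording lengths between classes
#'
#' Compares per-patient mean recording duration between the positive and
#' negative class with Welch's t-test (recording length differs markedly
#' by finding in the multi-site data, so length is a potential shortcut
#' feature worth auditing before transfer experiments).
#'
#' @param catalog A `dataset_catalog` with audio on disk.
#' @param task Label defining the two groups.
#' @return The `htest` object, with an extra `group_means` field (seconds).
#' @export
recording_length_test <- function(catalog, task = "outcome_binary") {
  labels <- catalog_labels(catalog, task)
  durs <- vapply(names(catalog$patients), function(pid) {
    p <- catalog$patients[[pid]]
    if (nrow(p$recordings) == 0) return(NA_real_)
    mean(vapply(p$recordings$file, function(f) {
      w <- read_wav(file.path(catalog$root, f))
      length(w$samples) / w$fs_hz
    }, numeric(1)))
  }, numeric(1))
  keep <- !is.na(durs) & !is.na(labels)
  ht <- stats::t.test(durs[keep & labels == 1], durs[keep & labels == 0])
  ht$group_means <- c(positive = mean(durs[keep & labels == 1]),
                      negative = mean(durs[keep & labels == 0]))
  ht
}

#' Zero-shot evaluation of a trained pipeline on a foreign catalog
#'
#' Runs the identical preprocessing and prediction path on a dataset the
#' pipeline never saw, with no parameter update; a guard verifies bitwise
#' that no trainable parameter was mutated, and errors otherwise. The
#' report's accuracy triple follows the (overall, positive-class,
#' negative-class) transfer-table convention.
#'
#' @param pipeline A trained `murmur_pipeline` (see [fit_pipeline()]).
#' @param foreign_catalog A `dataset_catalog` from another site.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` with an extra `triple` field
#'   `c(overall, positive, negative)`.
#' @export
zero_shot_eval <- function(pipeline, foreign_catalog, threshold = 0.5) {
  stopifnot(inherits(pipeline, "murmur_pipeline"))
  before <- serialize(list(pipeline$bbres$params,
                           pipeline$fusion), NULL)
  pred <- predict_pipeline(pipeline, foreign_catalog)
  after <- serialize(list(pipeline$bbres$params, pipeline$fusion), NULL)
  if (!identical(before, after))
    stop("zero-shot guard: trainable parameters were mutated during evaluation")
  labels <- catalog_labels(foreign_catalog, pipeline$task)
  labels <- labels[pred$patient_id]
  scores <- if ("p_fused" %in% names(pred) && !all(is.na(pred$p_fused)))
    pred$p_fused else pred$p_deep
  rep <- metrics_report(labels, scores, threshold)
  rep$triple <- c(overall = rep$acc_overall, positive = rep$acc_positive,
                  negative = rep$acc_negative)
  rep
}
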