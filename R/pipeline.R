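# End-to-end orchestration: fit the window classifier + fusion on a
# catalog, predict on (possibly foreign) catalogs, and run patient-grouped
# cross-validation.

#' Fit the full screening pipeline on a catalog
#'
#' Stages: preprocessing into log-mel windows, training the residual window
#' classifier on weak (patient-level) labels, MC-dropout window prediction,
#' two-stage mean aggregation to patient level, and (optionally) fusion of
#' the aggregated score with demographic and signal features via
#' gradient-boosted trees. The imputer and fusion model are fitted on the
#' training patients only.
#'
#' @param catalog A `dataset_catalog` of the training site.
#' @param task `"murmur_binary"` (Present and Unknown positive vs Absent)
#'   or `"outcome_binary"` (Abnormal positive). The two tasks share the
#'   identical pipeline; only the target differs.
#' @param params A [spectrogram_params()].
#' @param config A [bbres_config()].
#' @param fusion Train the multimodal fusion stage (default TRUE).
#' @param weighted Inverse-class-frequency sample weights in fusion.
#' @param include_std Feed the MC spread into fusion (default FALSE).
#' @param positive_murmur Murmur labels treated as positive.
#' @param seed Pipeline seed; stage seeds are derived as seed + 1 (network),
#'   seed + 2 (MC passes), seed + 3 (fusion).
#' @param verbose Print training progress.
#' @return Object of class `murmur_pipeline`.
#' @export
fit_pipeline <- function(catalog, task = "murmur_binary",
                         params = spectrogram_params(),
                         config = bbres_config(), fusion = TRUE,
                         weighted = FALSE, include_std = FALSE,
                         positive_murmur = c("Present", "Unknown"),
                         seed = config$seed, verbose = FALSE) {
  ws <- preprocess_catalog(catalog, params, task, positive_murmur)
  model <- build_bbres(config)
  model <- train_bbres(model, ws, seed = seed + 1L, verbose = verbose)
  wp <- predict_window_mc(model, ws, seed = seed + 2L)
  agg <- aggregate_patients(wp)

  fusion_model <- NULL
  imputer <- NULL
  feats <- NULL
  if (fusion) {
    pf <- patient_features(catalog, params,
                           patient_ids = agg$patient_id)
    imputer <- pf$imputer
    rows <- fusion_rows(agg, pf$features, include_std)
    labels <- catalog_labels(catalog, task, positive_murmur)[agg$patient_id]
    val_index <- which(agg$patient_id %in% model$val_patients)
    fusion_model <- train_fusion(rows, labels, weighted = weighted,
                                 val_index = val_index, seed = seed + 3L)
  }
  structure(list(task = task, params = params, bbres = model,
                 fusion = fusion_model, imputer = imputer,
                 include_std = include_std,
                 positive_murmur = positive_murmur, seed = seed),
            class = "murmur_pipeline")
}

#' @export
print.murmur_pipeline <- function(x, ...) {
  cat(sprintf("<murmur_pipeline task=%s> %s%s\n", x$task,
              x$bbres$config$backbone,
              if (is.null(x$fusion)) "" else " + fusion"))
  invisible(x)
}

#' Predict patient-level scores with a fitted pipeline
#'
#' Runs the identical preprocessing (resampling to the training rate,
#' normalisation, windowing, log-mel) and prediction path on any catalog;
#' no parameter is updated.
#'
#' @param pipeline A `murmur_pipeline`.
#' @param catalog A `dataset_catalog`.
#' @param patient_ids Optional subset of patients.
#' @param T MC passes (default the trained config's).
#' @param seed Seed for the MC dropout masks (default pipeline seed + 2).
#' @return Data frame: `patient_id`, `p_deep`, `p_deep_std`, `p_fused`
#'   (NA when the pipeline has no fusion stage), `task`.
#' @export
predict_pipeline <- function(pipeline, catalog, patient_ids = NULL, T = NULL,
                             seed = NULL) {
  stopifnot(inherits(pipeline, "murmur_pipeline"))
  cat2 <- if (is.null(patient_ids)) catalog else
    catalog_subset(catalog, patient_ids)
  ws <- preprocess_catalog(cat2, pipeline$params, pipeline$task,
                           pipeline$positive_murmur, require_labels = FALSE)
  wp <- predict_window_mc(pipeline$bbres, ws, T = T,
                          seed = seed %||% (pipeline$seed + 2L))
  agg <- aggregate_patients(wp)
  out <- data.frame(patient_id = agg$patient_id, p_deep = agg$p_deep,
                    p_deep_std = agg$p_deep_std, p_fused = NA_real_,
                    task = pipeline$task, stringsAsFactors = FALSE)
  if (!is.null(pipeline$fusion)) {
    pf <- patient_features(cat2, pipeline$params, imputer = pipeline$imputer,
                           patient_ids = agg$patient_id)
    rows <- fusion_rows(agg, pf$features, pipeline$include_std)
    out$p_fused <- predict_fused(pipeline$fusion, rows)
  }
  out
}

#' Patient-grouped stratified k-fold cross-validation of the pipeline
#'
#' For each fold the pipeline is fitted on the remaining patients and
#' evaluated on the fold; fold assignment is at patient granularity, so no
#' subject's windows span train and test. Reported as per-fold metric
#' reports plus the across-fold mean and standard deviation.
#'
#' @param catalog A `dataset_catalog`.
#' @param k Folds (default 10).
#' @param threshold Decision threshold for the confusion-based metrics.
#' @param use_fused Score the fused probability when available (default
#'   TRUE, falling back to the deep score).
#' @param seed Fold-assignment and pipeline seed.
#' @param ... Passed to [fit_pipeline()].
#' @return List of class `crossval_result`: `reports` (per fold),
#'   `summary` (mean/sd data frame), `folds` (patient assignment),
#'   `predictions` (pooled out-of-fold predictions).
#' @export
crossval_pipeline <- function(catalog, k = 10, threshold = 0.5,
                              use_fused = TRUE, seed = 1L, ...) {
  dots <- list(...)
  task <- dots$task %||% "murmur_binary"
  folds <- grouped_kfold(catalog, k = k, seed = seed, task = task)
  labels_all <- catalog_labels(catalog, task)
  reports <- list()
  preds <- list()
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(names(catalog$patients), test_ids)
    if (length(intersect(train_ids, test_ids)) > 0)
      stop("fold leakage detected")
    pl <- fit_pipeline(catalog_subset(catalog, train_ids),
                       seed = seed + 10L * f, ...)
    pr <- predict_pipeline(pl, catalog, patient_ids = test_ids)
    pr$fold <- f
    score <- if (use_fused && !all(is.na(pr$p_fused))) pr$p_fused else
      pr$p_deep
    lab <- labels_all[pr$patient_id]
    keep <- !is.na(lab)
    reports[[f]] <- metrics_report(lab[keep], score[keep], threshold)
    preds[[f]] <- pr
  }
  structure(list(reports = reports, summary = fold_summary(reports),
                 folds = folds, predictions = do.call(rbind, preds)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds\n", length(x$reports)))
  print(x$summary, digits = 4)
  invisible(x)
}
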