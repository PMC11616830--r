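# Patient-level aggregation of window scores and multimodal late fusion
# with gradient-boosted trees (xgboost).

#' Aggregate window predictions to patient level
#'
#' Arithmetic-mean aggregation in two stages by default: mean over windows
#' within each recording, then mean over recordings, so a patient with many
#' windows at one auscultation site is not over-weighted. `mode = "pooled"`
#' averages all windows directly. The MC uncertainty is propagated as the
#' mean of window standard deviations.
#'
#' @param window_preds Data frame from [predict_window_mc()] with columns
#'   `patient_id`, `recording_index`, `p_mean`, `p_std`.
#' @param mode `"two_stage"` (default) or `"pooled"`.
#' @return Data frame, one row per patient: `patient_id`, `p_deep`,
#'   `p_deep_std`, `n_windows`.
#' @export
aggregate_patients <- function(window_preds, mode = c("two_stage", "pooled")) {
  mode <- match.arg(mode)
  need <- c("patient_id", "recording_index", "p_mean", "p_std")
  if (!all(need %in% names(window_preds)))
    stop("window_preds must have columns ", paste(need, collapse = ", "))
  if (nrow(window_preds) == 0) stop("no window predictions to aggregate")
  agg_one <- function(df) {
    if (mode == "two_stage") {
      per_rec_p <- tapply(df$p_mean, df$recording_index, mean)
      per_rec_s <- tapply(df$p_std, df$recording_index, mean)
      data.frame(p_deep = mean(per_rec_p), p_deep_std = mean(per_rec_s),
                 n_windows = nrow(df))
    } else {
      data.frame(p_deep = mean(df$p_mean), p_deep_std = mean(df$p_std),
                 n_windows = nrow(df))
    }
  }
  parts <- lapply(split(window_preds, window_preds$patient_id), agg_one)
  out <- do.call(rbind, parts)
  out <- cbind(data.frame(patient_id = names(parts),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out[order(out$patient_id, method = "radix"), , drop = FALSE]
}

#' Train the gradient-boosted fusion classifier
#'
#' Fuses the aggregated deep score with demographic and signal features in
#' a binary xgboost model. `"weighted"` mode applies
#' inverse-class-frequency sample weights. Shallow trees with early
#' stopping on a held-out validation slice; these hyperparameters are this
#' package's defaults, not reported by the source work.
#'
#' @param rows Numeric feature matrix (one row per training patient; stable
#'   column order, first column conventionally `p_deep`).
#' @param labels Binary 0/1 vector.
#' @param weighted Apply inverse-class-frequency weights (default FALSE).
#' @param val_index Optional row indices used for early stopping; default a
#'   seeded 20% draw.
#' @param max_depth,nrounds,eta xgboost hyperparameters (defaults 3, 200,
#'   0.1; early stopping after 20 stagnant rounds).
#' @param seed RNG seed (xgboost runs single-threaded for reproducibility).
#' @return Object of class `fusion_model` wrapping the booster and the
#'   training column names.
#' @export
train_fusion <- function(rows, labels, weighted = FALSE, val_index = NULL,
                         max_depth = 3, nrounds = 200, eta = 0.1, seed = 1L) {
  rows <- as.matrix(rows)
  stopifnot(nrow(rows) == length(labels))
  if (length(unique(labels)) < 2)
    stop("fusion training requires both classes present")
  set.seed(seed)
  if (is.null(val_index)) {
    val_index <- sample(nrow(rows), max(2L, round(0.2 * nrow(rows))))
    # guarantee both classes in the fit slice
    if (length(unique(labels[-val_index])) < 2) val_index <- integer(0)
  }
  w <- rep(1, length(labels))
  if (weighted) {
    frac <- mean(labels)
    w <- ifelse(labels == 1, 1 / (2 * frac), 1 / (2 * (1 - frac)))
  }
  fit_idx <- setdiff(seq_len(nrow(rows)), val_index)
  dtrain <- xgboost::xgb.DMatrix(rows[fit_idx, , drop = FALSE],
                                 label = labels[fit_idx],
                                 weight = w[fit_idx])
  watch <- list(train = dtrain)
  early <- NULL
  if (length(val_index) >= 2 && length(unique(labels[val_index])) == 2) {
    watch$val <- xgboost::xgb.DMatrix(rows[val_index, , drop = FALSE],
                                      label = labels[val_index])
    early <- 20
  }
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, eval_metric = "logloss"),
    data = dtrain, nrounds = nrounds, evals = watch,
    early_stopping_rounds = early, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(rows),
                 weighted = weighted, seed = seed),
            class = "fusion_model")
}

#' Predict fused probabilities
#'
#' @param model A `fusion_model`.
#' @param rows Feature matrix with the training column layout.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_fused <- function(model, rows) {
  stopifnot(inherits(model, "fusion_model"))
  rows <- as.matrix(rows)
  if (ncol(rows) != length(model$feature_names))
    stop("feature width mismatch: model expects ",
         length(model$feature_names), " columns, got ", ncol(rows))
  predict(model$booster, xgboost::xgb.DMatrix(rows))
}

#' Assemble fusion feature rows
#'
#' Binds the aggregated deep score (and optionally its MC spread) to the
#' per-patient demographic + signal feature matrix, aligning by patient id.
#'
#' @param patient_preds Output of [aggregate_patients()].
#' @param features Matrix from [patient_features()] (rownames = patient ids).
#' @param include_std Include `p_deep_std` as a feature (default FALSE; the
#'   source pipeline's use of the uncertainty as a fusion input is
#'   unstated).
#' @return Numeric matrix, rownames = patient ids.
#' @export
fusion_rows <- function(patient_preds, features, include_std = FALSE) {
  ids <- patient_preds$patient_id
  missing_ids <- setdiff(ids, rownames(features))
  if (length(missing_ids) > 0)
    stop("no features for patient(s): ", paste(missing_ids, collapse = ", "))
  deep <- if (include_std) {
    cbind(p_deep = patient_preds$p_deep, p_deep_std = patient_preds$p_deep_std)
  } else {
    cbind(p_deep = patient_preds$p_deep)
  }
  out <- cbind(deep, features[ids, , drop = FALSE])
  rownames(out) <- ids
  out
}
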