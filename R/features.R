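# Tabular features for the fusion stage: demographic encoding with mean
# imputation, and audio summary statistics in the time and frequency domains.

.DEMO_FIELDS <- c("age_months", "sex_female", "sex_male", "pregnant",
                  "height_cm", "weight_kg")
.DEMO_NUMERIC <- c("age_months", "height_cm", "weight_kg")

# Approximate age-group midpoints in months, following the challenge
# baseline convention. Configurable via the `age_months_map` argument.
.AGE_MONTHS <- c(Neonate = 0.5, Infant = 6, Child = 72, Adolescent = 180)

#' Encode patient demographics as a numeric vector
#'
#' Age categories map to approximate month equivalents (Neonate 0.5,
#' Infant 6, Child 72, Adolescent 180 by default), sex is one-hot encoded
#' (both columns zero when missing), pregnancy becomes 0/1 (missing counts
#' as 0). Numeric fields that are missing stay `NA` here and are filled by
#' the fold-fitted imputer; the missingness mask is returned alongside.
#'
#' @param record A [patient_record()].
#' @param age_months_map Named vector mapping age groups to months.
#' @return List with `values` (named numeric vector over
#'   `age_months, sex_female, sex_male, pregnant, height_cm, weight_kg`)
#'   and logical `missing_mask` of the same length.
#' @export
encode_demographics <- function(record, age_months_map = .AGE_MONTHS) {
  stopifnot(inherits(record, "patient_record"))
  v <- stats::setNames(numeric(length(.DEMO_FIELDS)), .DEMO_FIELDS)
  m <- stats::setNames(logical(length(.DEMO_FIELDS)), .DEMO_FIELDS)

  if (record$age_group %in% names(age_months_map)) {
    v["age_months"] <- age_months_map[[record$age_group]]
  } else {
    v["age_months"] <- NA_real_; m["age_months"] <- TRUE
  }
  if (record$sex == "Female") v["sex_female"] <- 1
  if (record$sex == "Male") v["sex_male"] <- 1
  if (record$sex == "Missing") m[c("sex_female", "sex_male")] <- TRUE
  v["pregnant"] <- if (isTRUE(record$pregnant)) 1 else 0
  m["pregnant"] <- is.na(record$pregnant)
  v["height_cm"] <- record$height_cm
  m["height_cm"] <- is.na(record$height_cm)
  v["weight_kg"] <- record$weight_kg
  m["weight_kg"] <- is.na(record$weight_kg)
  list(values = v, missing_mask = m)
}

#' Fit a mean imputer on training demographic vectors
#'
#' Means are computed over observed values of the numeric fields
#' (`age_months`, `height_cm`, `weight_kg`) of the *training* rows only, so
#' no test-fold information ever leaks into imputation. Categorical one-hot
#' columns are not imputed (all-zero encodes missingness).
#'
#' @param demo_list List of [encode_demographics()] results (training rows).
#' @return Object of class `mean_imputer` holding per-field means.
#' @export
fit_imputer <- function(demo_list) {
  stopifnot(length(demo_list) >= 1)
  means <- vapply(.DEMO_NUMERIC, function(f) {
    obs <- vapply(demo_list, function(d) {
      if (d$missing_mask[[f]]) NA_real_ else d$values[[f]]
    }, numeric(1))
    if (all(is.na(obs)))
      stop("field '", f, "' is missing in every training row; cannot impute")
    mean(obs, na.rm = TRUE)
  }, numeric(1))
  structure(list(means = means), class = "mean_imputer")
}

#' Apply a fitted mean imputer to one demographic vector
#' @param imputer A `mean_imputer` from [fit_imputer()].
#' @param demo An [encode_demographics()] result.
#' @return Named numeric vector with no `NA`s.
#' @export
apply_imputer <- function(imputer, demo) {
  stopifnot(inherits(imputer, "mean_imputer"))
  v <- demo$values
  for (f in .DEMO_NUMERIC) {
    if (demo$missing_mask[[f]] || is.na(v[[f]])) v[f] <- imputer$means[[f]]
  }
  v
}

.SIGFEAT_NAMES <- c("amp_mean", "amp_sd", "amp_skewness", "amp_kurtosis",
                    "rms", "zcr_hz",
                    "spec_centroid_mean_hz", "spec_centroid_sd_hz",
                    "spec_rolloff_mean_hz", "spec_rolloff_sd_hz",
                    "spec_bandwidth_mean_hz", "spec_bandwidth_sd_hz",
                    "dominant_freq_hz")

#' Audio summary features of one recording
#'
#' Time-domain: mean, standard deviation, skewness, kurtosis, RMS, and
#' zero-crossing rate (crossings per second, Hz). Frequency-domain, from
#' framed STFT magnitude spectra (25 ms window, 10 ms hop): spectral
#' centroid `sum(f |S(f)|) / sum |S(f)|`, roll-off frequency at
#' `rolloff_pct` cumulative energy (default 85%), and bandwidth (the
#' energy-weighted standard deviation around the centroid), each summarised
#' as mean and SD over frames, plus the dominant frequency (argmax of the
#' mean power spectrum). Spectral moments are invariant to the amplitude
#' scale of the input, so per-recording peak normalisation does not affect
#' them.
#'
#' @param recording A [pcg_recording()] (already resampled/normalised in the
#'   pipeline; any rate is accepted here).
#' @param rolloff_pct Cumulative-energy fraction for the roll-off (0-1).
#' @return Named numeric vector of 13 features with attribute
#'   `degenerate` flagging an all-zero input (features all zero then).
#' @export
signal_features <- function(recording, rolloff_pct = 0.85) {
  stopifnot(inherits(recording, "pcg_recording"),
            rolloff_pct > 0, rolloff_pct <= 1)
  x <- recording$samples
  fs <- recording$fs_hz
  out <- stats::setNames(numeric(length(.SIGFEAT_NAMES)), .SIGFEAT_NAMES)
  if (all(x == 0)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out["amp_mean"] <- mean(x)
  out["amp_sd"] <- stats::sd(x)
  out["amp_skewness"] <- e1071::skewness(x)
  out["amp_kurtosis"] <- e1071::kurtosis(x)
  out["rms"] <- sqrt(mean(x^2))
  out["zcr_hz"] <- sum(diff(sign(x[x != 0])) != 0) * fs / (2 * length(x))

  st <- .stft_power(x, fs, 25, 10)
  p <- st$power                      # bins x frames
  f <- st$freqs
  tot <- colSums(p)
  ok <- tot > 0
  centroid <- rep(NA_real_, ncol(p))
  centroid[ok] <- colSums(p[, ok, drop = FALSE] * f) / tot[ok]
  cumfrac <- apply(p[, ok, drop = FALSE], 2, function(col) {
    f[which(cumsum(col) >= rolloff_pct * sum(col))[1]]
  })
  bw <- vapply(which(ok), function(j) {
    sqrt(sum(p[, j] * (f - centroid[j])^2) / tot[j])
  }, numeric(1))
  out["spec_centroid_mean_hz"] <- mean(centroid, na.rm = TRUE)
  out["spec_centroid_sd_hz"] <- stats::sd(centroid[ok])
  out["spec_rolloff_mean_hz"] <- mean(cumfrac)
  out["spec_rolloff_sd_hz"] <- stats::sd(cumfrac)
  out["spec_bandwidth_mean_hz"] <- mean(bw)
  out["spec_bandwidth_sd_hz"] <- stats::sd(bw)
  out["dominant_freq_hz"] <- f[which.max(rowMeans(p))]
  out[is.na(out)] <- 0
  attr(out, "degenerate") <- FALSE
  out
}

#' Per-patient feature matrix for the fusion stage
#'
#' Encodes demographics for every patient, computes signal features per
#' recording (after resampling to the spectrogram target rate and peak
#' normalisation) and aggregates them by the unweighted mean over
#' recordings, so the dimension is constant regardless of how many
#' locations a patient has.
#'
#' @param catalog A `dataset_catalog`.
#' @param params A [spectrogram_params()] (for the target rate).
#' @param imputer Optional pre-fitted `mean_imputer`; when `NULL` one is
#'   fitted on these patients (training use).
#' @param patient_ids Patients to include (default all).
#' @return List with `features` (matrix, one row per patient, stable column
#'   order: demographics then signal features), `imputer`.
#' @export
patient_features <- function(catalog, params = spectrogram_params(),
                             imputer = NULL, patient_ids = NULL) {
  ids <- patient_ids %||% names(catalog$patients)
  demos <- lapply(ids, function(pid)
    encode_demographics(catalog$patients[[pid]]))
  if (is.null(imputer)) imputer <- fit_imputer(demos)
  demo_mat <- t(vapply(demos, function(d) apply_imputer(imputer, d),
                       numeric(length(.DEMO_FIELDS))))
  sig_mat <- t(vapply(ids, function(pid) {
    p <- catalog$patients[[pid]]
    if (nrow(p$recordings) == 0)
      return(stats::setNames(numeric(length(.SIGFEAT_NAMES)),
                             .SIGFEAT_NAMES))
    recs <- patient_recordings(catalog, p)
    feats <- vapply(recs, function(r) {
      r <- resample_recording(r, params$target_fs_hz)
      r$samples <- as.numeric(normalize_amplitude(r$samples))
      signal_features(r)
    }, numeric(length(.SIGFEAT_NAMES)))
    rowMeans(feats)
  }, numeric(length(.SIGFEAT_NAMES))))
  feats <- cbind(demo_mat, sig_mat)
  rownames(feats) <- ids
  colnames(feats) <- c(.DEMO_FIELDS, .SIGFEAT_NAMES)
  list(features = feats, imputer = imputer)
}

#' Export a per-patient feature matrix as CSV
#'
#' Writes the matrix from [patient_features()] with a leading `patient_id`
#' column; the column order is the documented stable order (demographics,
#' then signal features).
#'
#' @param features Feature matrix with patient-id rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(patient_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
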