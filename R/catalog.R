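# In-memory catalog model for PhysioNet-challenge-style heart-sound datasets.
# A catalog holds one patient_record per subject; audio stays on disk until
# read_recording() is called, so label tallies never require decoding WAVs.

.AGE_GROUPS <- c("Neonate", "Infant", "Child", "Adolescent", "Missing")
.SEXES      <- c("Female", "Male", "Missing")
.MURMURS    <- c("Present", "Absent", "Unknown", "Missing")
.OUTCOMES   <- c("Normal", "Abnormal", "Missing")
.LOCATIONS  <- c("AV", "PV", "TV", "MV", "Phc")
.SCHEMAS    <- c("circor2022", "cinc2016", "yaseen", "synthetic")

#' Construct a patient record
#'
#' One subject of a heart-sound dataset: demographics, the murmur and
#' clinical-outcome labels, and references to up to six auscultation-location
#' recordings.
#'
#' @param patient_id Unique identifier (string).
#' @param age_group One of `"Neonate"`, `"Infant"`, `"Child"`,
#'   `"Adolescent"`, `"Missing"`.
#' @param sex `"Female"`, `"Male"` or `"Missing"`.
#' @param height_cm,weight_kg Positive numbers or `NA` when missing.
#' @param pregnant `TRUE`/`FALSE`/`NA`.
#' @param murmur `"Present"`, `"Absent"`, `"Unknown"` or `"Missing"`.
#' @param outcome `"Normal"`, `"Abnormal"` or `"Missing"`.
#' @param recordings Data frame with columns `location` and `file`
#'   (paths relative to the dataset root), zero to six rows.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, age_group = "Missing", sex = "Missing",
                           height_cm = NA_real_, weight_kg = NA_real_,
                           pregnant = NA, murmur = "Missing",
                           outcome = "Missing",
                           recordings = data.frame(location = character(),
                                                   file = character())) {
  rec <- structure(list(
    patient_id = as.character(patient_id),
    age_group = age_group, sex = sex,
    height_cm = as.numeric(height_cm), weight_kg = as.numeric(weight_kg),
    pregnant = if (is.na(pregnant)) NA else isTRUE(pregnant),
    murmur = murmur, outcome = outcome,
    recordings = recordings
  ), class = "patient_record")
  validate_patient_record(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient %s> age=%s sex=%s murmur=%s outcome=%s recordings=%d\n",
              x$patient_id, x$age_group, x$sex, x$murmur, x$outcome,
              nrow(x$recordings)))
  invisible(x)
}

validate_patient_record <- function(rec) {
  if (!nzchar(rec$patient_id)) stop("patient_id must be non-empty")
  if (!rec$age_group %in% .AGE_GROUPS)
    stop("invalid age group: ", rec$age_group)
  if (!rec$sex %in% .SEXES) stop("invalid sex: ", rec$sex)
  if (!rec$murmur %in% .MURMURS) stop("invalid murmur label: ", rec$murmur)
  if (!rec$outcome %in% .OUTCOMES) stop("invalid outcome label: ", rec$outcome)
  if (!is.na(rec$height_cm) && rec$height_cm <= 0)
    stop("height must be strictly positive")
  if (!is.na(rec$weight_kg) && rec$weight_kg <= 0)
    stop("weight must be strictly positive")
  if (nrow(rec$recordings) > 6)
    stop("at most six recording locations per patient")
  if (nrow(rec$recordings) > 0 &&
      !all(rec$recordings$location %in% .LOCATIONS))
    stop("invalid recording location(s): ",
         paste(setdiff(rec$recordings$location, .LOCATIONS), collapse = ", "))
  rec
}

#' Construct an in-memory recording
#'
#' @param samples Numeric amplitude vector (dimensionless).
#' @param fs_hz Positive integer sampling rate.
#' @param location Auscultation site, one of `"AV"`, `"PV"`, `"TV"`, `"MV"`,
#'   `"Phc"` (unspecified).
#' @return An object of class `pcg_recording` with a `duration_s` field.
#' @export
pcg_recording <- function(samples, fs_hz, location = "Phc") {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  fs_hz <- as.integer(fs_hz)
  if (is.na(fs_hz) || fs_hz < 1) stop("fs_hz must be a positive integer")
  if (!location %in% .LOCATIONS) stop("invalid recording location: ", location)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 location = location,
                 duration_s = length(samples) / fs_hz),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<recording %s> %.2f s at %d Hz (%d samples)\n",
              x$location, x$duration_s, x$fs_hz, length(x$samples)))
  invisible(x)
}

#' Parse a plain-text patient header
#'
#' Parses the key:value patient-header dialect used by the 2022-challenge
#' layout (and by synthetic cohorts written with [generate_cohort()]):
#' a first line `<patient_id> <n_recordings> <fs>`, one line per recording
#' naming the location tag and WAV file, then `#Key: value` metadata lines.
#' Unparseable numeric values (e.g. `"NA"`, `"nan"`) map to missing rather
#' than erroring; around 13% of real metadata is missing, so missingness is
#' an expected state, not a fault.
#'
#' @param text Header content as a single string or character vector of lines.
#' @param schema Dataset schema; only the `"circor2022"` dialect (also used
#'   by `"synthetic"`) is a text header.
#' @return A [patient_record()].
#' @export
parse_patient_header <- function(text, schema = "circor2022") {
  if (!schema %in% c("circor2022", "synthetic"))
    stop("no text-header dialect for schema: ", schema)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty patient header")

  head_tok <- strsplit(lines[1], "[[:space:]]+")[[1]]
  if (length(head_tok) < 2 || is.na(suppressWarnings(as.integer(head_tok[2]))))
    stop("malformed header line: '", lines[1], "'")
  pid <- head_tok[1]
  n_rec <- as.integer(head_tok[2])
  if (n_rec > 6) stop("malformed header line (more than six recordings): '",
                      lines[1], "'")
  if (length(lines) < 1 + n_rec)
    stop("header declares ", n_rec, " recordings but has ",
         length(lines) - 1, " lines")

  loc <- character(n_rec); file <- character(n_rec)
  for (i in seq_len(n_rec)) {
    tok <- strsplit(lines[1 + i], "[[:space:]]+")[[1]]
    wav <- tok[grepl("\\.wav$", tok, ignore.case = TRUE)]
    if (length(tok) < 2 || length(wav) == 0)
      stop("malformed recording line: '", lines[1 + i], "'")
    loc[i] <- if (tok[1] %in% .LOCATIONS) tok[1] else "Phc"
    file[i] <- wav[1]
  }

  meta <- list()
  for (ln in lines[grepl("^#", lines)]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed metadata line: '", ln, "'")
    meta[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }

  get_enum <- function(key, domain, default = "Missing") {
    v <- meta[[key]]
    if (is.null(v) || v %in% c("", "NA", "nan", "None")) return(default)
    if (!v %in% domain)
      stop("validation error: unknown ", key, " value '", v, "'")
    v
  }
  get_num <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) return(NA_real_)
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num) || !is.finite(num)) NA_real_ else num
  }
  get_bool <- function(key) {
    v <- meta[[key]]
    if (is.null(v) || v %in% c("", "NA", "nan", "None")) return(NA)
    tolower(v) %in% c("true", "yes", "1")
  }

  patient_record(
    patient_id = pid,
    age_group = get_enum("age", .AGE_GROUPS),
    sex = get_enum("sex", .SEXES),
    height_cm = get_num("height"),
    weight_kg = get_num("weight"),
    pregnant = get_bool("pregnancy status"),
    murmur = get_enum("murmur", .MURMURS),
    outcome = get_enum("outcome", .OUTCOMES),
    recordings = data.frame(location = loc, file = file,
                            stringsAsFactors = FALSE)
  )
}

#' Read one WAV recording from disk
#'
#' @param path WAV file path.
#' @param expected_fs Optional sampling rate; a mismatch with the container
#'   metadata is an error (catches e.g. 2000 Hz files fed to a 4000 Hz
#'   pipeline stage without resampling).
#' @param location Auscultation location tag to attach.
#' @return A [pcg_recording()].
#' @export
read_recording <- function(path, expected_fs = NULL, location = "Phc") {
  w <- read_wav(path)
  if (!is.null(expected_fs) && w$fs_hz != expected_fs)
    stop("sampling-rate mismatch: file ", path, " has ", w$fs_hz,
         " Hz, expected ", expected_fs, " Hz")
  pcg_recording(w$samples, w$fs_hz, location)
}

#' Scan a dataset tree into a catalog
#'
#' Supported layouts: `"circor2022"`/`"synthetic"` (one `<patient_id>.txt`
#' header per subject plus per-location WAVs) and `"cinc2016"` (one WAV per
#' record plus a `REFERENCE.csv` of `name,label` rows with label 1 =
#' abnormal, -1 = normal; each record becomes its own single-recording
#' patient, since subject identifiers are largely unavailable in that
#' layout). Patients are ordered lexicographically by id so downstream
#' seeded operations are reproducible.
#'
#' @param root Dataset root directory.
#' @param schema One of `"circor2022"`, `"cinc2016"`, `"yaseen"`,
#'   `"synthetic"`.
#' @return An object of class `dataset_catalog` with fields `patients`
#'   (named list of [patient_record()]), `schema`, `root`.
#' @export
scan_dataset <- function(root, schema = "circor2022") {
  schema <- match.arg(schema, .SCHEMAS)
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  patients <- switch(schema,
    circor2022 = ,
    synthetic = .scan_header_layout(root, schema),
    cinc2016 = .scan_reference_layout(root),
    yaseen = .scan_reference_layout(root)
  )
  ids <- vapply(patients, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids, method = "radix")
  patients <- patients[ord]
  names(patients) <- ids[ord]
  if (length(patients) == 0)
    warning("no patients found under ", root, " for schema ", schema)
  structure(list(patients = patients, schema = schema,
                 root = normalizePath(root)),
            class = "dataset_catalog")
}

.scan_header_layout <- function(root, schema) {
  headers <- sort(list.files(root, pattern = "\\.txt$", full.names = TRUE))
  lapply(headers, function(h) {
    parse_patient_header(readLines(h, warn = FALSE), schema = "circor2022")
  })
}

.scan_reference_layout <- function(root) {
  ref_path <- file.path(root, "REFERENCE.csv")
  if (!file.exists(ref_path)) {
    if (length(list.files(root)) == 0) return(list())
    stop("cinc2016-style layout requires REFERENCE.csv under ", root)
  }
  ref <- utils::read.csv(ref_path, header = FALSE,
                         col.names = c("name", "label"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(ref)), function(i) {
    patient_record(
      patient_id = ref$name[i],
      outcome = if (ref$label[i] == 1) "Abnormal" else "Normal",
      recordings = data.frame(location = "Phc",
                              file = paste0(ref$name[i], ".wav"),
                              stringsAsFactors = FALSE)
    )
  })
}

#' @export
print.dataset_catalog <- function(x, ...) {
  s <- catalog_summary(x)
  cat(sprintf("<dataset_catalog schema=%s> %d patients, %d recordings\n",
              x$schema, s$n_patients, s$n_recordings))
  cat("  murmur: ", paste(names(s$murmur), unlist(s$murmur),
                          sep = "=", collapse = " "), "\n")
  cat("  outcome:", paste(names(s$outcome), unlist(s$outcome),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Label tallies and size of a catalog
#'
#' Computed from headers only; no audio is read.
#'
#' @param catalog A `dataset_catalog`.
#' @return List with `n_patients`, `n_recordings`, and named count lists
#'   `murmur`, `outcome`, `age_group`.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "dataset_catalog"))
  tally <- function(field, domain) {
    v <- vapply(catalog$patients, `[[`, "", field)
    as.list(table(factor(v, levels = domain)))
  }
  list(
    n_patients = length(catalog$patients),
    n_recordings = sum(vapply(catalog$patients,
                              function(p) nrow(p$recordings), 0L)),
    murmur = tally("murmur", .MURMURS),
    outcome = tally("outcome", .OUTCOMES),
    age_group = tally("age_group", .AGE_GROUPS)
  )
}

#' Write catalog summary as JSON
#' @param catalog A `dataset_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_summary <- function(catalog, path) {
  jsonlite::write_json(catalog_summary(catalog), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write patient-level predictions to CSV
#'
#' Columns: `patient_id`, `task`, `score`, `label_at_threshold`, `mc_std`.
#' Scores are written with enough digits to round-trip at 1e-6 precision.
#'
#' @param catalog The catalog the predictions refer to (membership check).
#' @param predictions Data frame with columns `patient_id`, `task`, `score`
#'   and optionally `mc_std`.
#' @param path Output CSV path.
#' @param threshold Decision threshold applied for `label_at_threshold`
#'   (score >= threshold is positive).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(catalog, predictions, path, threshold = 0.5) {
  stopifnot(inherits(catalog, "dataset_catalog"), is.data.frame(predictions))
  need <- c("patient_id", "task", "score")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns ", paste(need, collapse = ", "))
  unknown <- setdiff(predictions$patient_id, names(catalog$patients))
  if (length(unknown) > 0)
    stop("prediction for unknown patient_id: ",
         paste(unknown, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(predictions$patient_id),
    task = as.character(predictions$task),
    score = sprintf("%.8f", predictions$score),
    label_at_threshold = as.integer(predictions$score >= threshold),
    mc_std = sprintf("%.8f", if ("mc_std" %in% names(predictions))
      predictions$mc_std else rep(0, nrow(predictions))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a predictions CSV written by [write_predictions()]
#' @param path CSV path.
#' @return Data frame with numeric `score` and `mc_std`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  df$score <- as.numeric(df$score)
  df$mc_std <- as.numeric(df$mc_std)
  df
}

#' Binary task labels of a catalog
#'
#' @param catalog A `dataset_catalog`.
#' @param task `"murmur_binary"` (positive when the murmur label is in
#'   `positive_murmur`) or `"outcome_binary"` (positive = Abnormal).
#' @param positive_murmur Murmur labels counted positive.
#' @return Named integer vector (0/1, `NA` where the label is Missing),
#'   ordered like `catalog$patients`.
#' @export
catalog_labels <- function(catalog, task = c("murmur_binary", "outcome_binary"),
                           positive_murmur = c("Present", "Unknown")) {
  task <- match.arg(task)
  vapply(catalog$patients, function(p) {
    if (task == "murmur_binary") {
      if (p$murmur == "Missing") return(NA_integer_)
      as.integer(p$murmur %in% positive_murmur)
    } else {
      if (p$outcome == "Missing") return(NA_integer_)
      as.integer(p$outcome == "Abnormal")
    }
  }, integer(1))
}

#' Subset a catalog to a set of patients
#'
#' @param catalog A `dataset_catalog`.
#' @param ids Patient ids to keep; catalog order is preserved.
#' @return A `dataset_catalog` with only those patients.
#' @export
catalog_subset <- function(catalog, ids) {
  keep <- names(catalog$patients) %in% ids
  out <- catalog
  out$patients <- catalog$patients[keep]
  out
}

# Internal: read all recordings of one patient from disk.
patient_recordings <- function(catalog, patient, expected_fs = NULL) {
  recs <- patient$recordings
  lapply(seq_len(nrow(recs)), function(i) {
    read_recording(file.path(catalog$root, recs$file[i]),
                   expected_fs = expected_fs, location = recs$location[i])
  })
}
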