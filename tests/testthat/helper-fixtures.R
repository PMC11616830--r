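# Shared fixtures: desk-scale synthetic cohorts and parameter sets.
# Desk-scale study conditions (chosen once): 6-9 s recordings, 1-2
# auscultation locations per patient, 32 mel bands, lite backbone.

desk_sim <- function(duration = c(6, 9), snr_db = 10) {
  sim_config(duration_s_range = duration, murmur_snr_db = snr_db)
}

desk_cohort <- function(n, locations = c(1, 2)) {
  cohort_config(n, n_locations_range = locations)
}

desk_params <- function() spectrogram_params(n_mels = 32)

make_cohort <- function(n = 24, seed = 1, dir = withr::local_tempdir(.local_envir = parent.frame()),
                        snr_db = 10, locations = c(1, 2)) {
  suppressWarnings(generate_cohort(desk_cohort(n, locations),
                                   desk_sim(snr_db = snr_db),
                                   dir, seed = seed, force = TRUE))
}

# A label-only catalog (no audio on disk) for protocol tests.
label_catalog <- function(n_pos, n_neg, task = "outcome_binary") {
  n <- n_pos + n_neg
  ids <- sprintf("S%05d", seq_len(n))
  outcome <- c(rep("Abnormal", n_pos), rep("Normal", n_neg))
  murmur <- c(rep("Present", n_pos), rep("Absent", n_neg))
  patients <- lapply(seq_len(n), function(i) {
    patient_record(ids[i], murmur = murmur[i], outcome = outcome[i])
  })
  names(patients) <- ids
  structure(list(patients = patients, schema = "synthetic", root = "."),
            class = "dataset_catalog")
}

# Tiny separable window set for learnability smoke tests: positive windows
# carry a bright horizontal band, negatives are noise.
separable_windows <- function(n_patients = 16, windows_per = 3, seed = 1,
                              h = 32, w = 60) {
  set.seed(seed)
  n <- n_patients * windows_per
  imgs <- array(stats::runif(h * w * n, 0, 0.4), c(h, w, n))
  labels <- rep(rep(c(0L, 1L), length.out = n_patients), each = windows_per)
  for (i in which(labels == 1)) {
    imgs[10:14, , i] <- imgs[10:14, , i] + 0.6
  }
  meta <- data.frame(
    patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                     each = windows_per),
    recording_index = 1L,
    offset_s = rep(seq_len(windows_per) - 1, n_patients),
    label = labels, stringsAsFactors = FALSE)
  structure(list(images = imgs, meta = meta, params = desk_params(),
                 excluded = character()),
            class = "window_set")
}

fast_config <- function(epochs = 2, seed = 7, mc_passes = 3, ...) {
  bbres_config(epochs = epochs, lr = 2e-3, seed = seed,
               mc_passes = mc_passes, ...)
}
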