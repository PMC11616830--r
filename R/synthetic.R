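# Synthetic phonocardiogram cohorts: S1/S2 transients on a periodic cycle,
# band-limited systolic murmur noise for positive cases, ambient noise, and
# header/label statistics matching the screening dataset's published joint
# distribution. Physiological realism is a non-goal: the generator exists to
# give the pipeline a controllable, learnable class difference and the same
# on-disk layout and label imbalance as the real data.

#' Simulation parameters for one synthetic recording
#'
#' @param fs_hz Sampling rate (default 4000).
#' @param duration_s_range Recording length range in seconds (default
#'   `c(5, 80)`, the range of the screening dataset).
#' @param heart_rate_bpm_range Heart rate range (default `c(70, 140)`,
#'   paediatric resting rates).
#' @param s1_s2_freq_range Centre frequency range of the S1/S2 damped
#'   sinusoids in Hz (default `c(50, 150)`).
#' @param s1_s2_dur_range Transient duration range in seconds (default
#'   `c(0.03, 0.05)`).
#' @param murmur_band_hz Murmur noise band (default `c(150, 400)` Hz,
#'   band-passed Gaussian noise gated to systole).
#' @param murmur_snr_db Murmur band power in systole relative to the
#'   ambient noise floor in the same band, in dB (default 10).
#' @param unknown_snr_penalty_db How much quieter an "Unknown"-label murmur
#'   is than a "Present" one (default 12 dB), so the Present-or-Unknown
#'   binary grouping stays meaningful but Unknown cases are genuinely hard.
#' @param ambient_noise_db Ambient white-noise level relative to the unit
#'   S1 peak, in dB (default -25).
#' @param systole_fraction Fraction of the cycle between S1 onset and S2
#'   onset (default 0.35).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 4000, duration_s_range = c(5, 80),
                       heart_rate_bpm_range = c(70, 140),
                       s1_s2_freq_range = c(50, 150),
                       s1_s2_dur_range = c(0.03, 0.05),
                       murmur_band_hz = c(150, 400), murmur_snr_db = 10,
                       unknown_snr_penalty_db = 12, ambient_noise_db = -25,
                       systole_fraction = 0.35) {
  stopifnot(fs_hz %% 2 == 0, duration_s_range[1] <= duration_s_range[2],
            is.finite(murmur_snr_db), murmur_band_hz[1] < murmur_band_hz[2],
            murmur_band_hz[2] < fs_hz / 2)
  structure(list(fs_hz = as.integer(fs_hz),
                 duration_s_range = duration_s_range,
                 heart_rate_bpm_range = heart_rate_bpm_range,
                 s1_s2_freq_range = s1_s2_freq_range,
                 s1_s2_dur_range = s1_s2_dur_range,
                 murmur_band_hz = murmur_band_hz,
                 murmur_snr_db = murmur_snr_db,
                 unknown_snr_penalty_db = unknown_snr_penalty_db,
                 ambient_noise_db = ambient_noise_db,
                 systole_fraction = systole_fraction),
            class = "sim_config")
}

#' Cohort-level label and demographic distribution
#'
#' Defaults reproduce the published training-cohort statistics: murmur
#' prevalence Absent/Unknown/Present = 0.738/0.072/0.190, outcome
#' conditionals P(Abnormal | Present) = 150/179, P(Abnormal | Absent) =
#' 263/695, P(Abnormal | Unknown) = 43/68, age-group frequencies
#' 6/126/664/72/74 out of 942, and a 13% metadata missingness rate (age,
#' height and weight going missing together, as observed in the real data).
#'
#' @param n_patients Cohort size.
#' @param murmur_prev Named probability vector over Absent/Unknown/Present.
#' @param p_abnormal_given Named vector of P(Abnormal | murmur label).
#' @param age_freq Named probability vector over age groups (incl. Missing).
#' @param missing_rate Probability a patient's numeric metadata is missing.
#' @param n_locations_range Recordings per patient (default `c(1, 6)`).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          murmur_prev = c(Absent = 0.738, Unknown = 0.072,
                                          Present = 0.190),
                          p_abnormal_given = c(Present = 150 / 179,
                                               Absent = 263 / 695,
                                               Unknown = 43 / 68),
                          age_freq = c(Neonate = 6, Infant = 126,
                                       Child = 664, Adolescent = 72,
                                       Missing = 74) / 942,
                          missing_rate = 0.13,
                          n_locations_range = c(1, 6)) {
  stopifnot(abs(sum(murmur_prev) - 1) < 1e-6,
            all(p_abnormal_given >= 0 & p_abnormal_given <= 1),
            abs(sum(age_freq) - 1) < 1e-6,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 murmur_prev = murmur_prev,
                 p_abnormal_given = p_abnormal_given,
                 age_freq = age_freq, missing_rate = missing_rate,
                 n_locations_range = as.integer(n_locations_range)),
            class = "cohort_config")
}

# Typical height (cm) and weight (kg) by age group: mean and SD.
.ANTHRO <- list(Neonate = c(h = 50, hs = 3, w = 3.5, ws = 0.6),
                Infant = c(h = 68, hs = 6, w = 8, ws = 1.5),
                Child = c(h = 115, hs = 15, w = 22, ws = 7),
                Adolescent = c(h = 160, hs = 10, w = 50, ws = 10))

#' Simulate one phonocardiogram recording
#'
#' The waveform is a sum over cardiac cycles of S1 and S2 damped-sinusoid
#' transients, plus (for murmur-positive cases) band-limited Gaussian noise
#' gated to systole at the configured SNR over the ambient floor, plus
#' ambient white noise; the result is peak-normalised. Deterministic given
#' the RNG state (or `seed`).
#'
#' @param simcfg A [sim_config()].
#' @param murmur_present Plant a systolic murmur?
#' @param location Auscultation tag for the result.
#' @param snr_db Override of `simcfg$murmur_snr_db` (used for
#'   "Unknown"-label low-SNR cases).
#' @param seed Optional seed.
#' @return A [pcg_recording()] with attribute `systole_mask` (logical,
#'   per sample) for band-power oracles.
#' @export
simulate_recording <- function(simcfg, murmur_present = FALSE,
                               location = "Phc", snr_db = NULL,
                               seed = NULL) {
  stopifnot(inherits(simcfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- simcfg$fs_hz
  dur <- stats::runif(1, simcfg$duration_s_range[1],
                      simcfg$duration_s_range[2])
  n <- as.integer(round(dur * fs))
  hr <- stats::runif(1, simcfg$heart_rate_bpm_range[1],
                     simcfg$heart_rate_bpm_range[2])
  cycle <- 60 / hr
  t_cycle_starts <- seq(0, dur, by = cycle)

  x <- numeric(n)
  systole <- logical(n)
  add_transient <- function(x, t0, amp) {
    f <- stats::runif(1, simcfg$s1_s2_freq_range[1],
                      simcfg$s1_s2_freq_range[2])
    d <- stats::runif(1, simcfg$s1_s2_dur_range[1],
                      simcfg$s1_s2_dur_range[2])
    i0 <- as.integer(round(t0 * fs)) + 1L
    idx <- i0:min(n, i0 + as.integer(d * fs))
    tt <- (idx - i0) / fs
    x[idx] <- x[idx] + amp * exp(-tt / (d / 4)) * sin(2 * pi * f * tt)
    x
  }
  for (t0 in t_cycle_starts) {
    if (round(t0 * fs) >= n) break
    x <- add_transient(x, t0, amp = 1)
    t_s2 <- t0 + simcfg$systole_fraction * cycle
    if (round(t_s2 * fs) < n) x <- add_transient(x, t_s2, amp = 0.8)
    sys_idx <- seq.int(as.integer(round((t0 + 0.05) * fs)) + 1L,
                       min(n, as.integer(round(t_s2 * fs))))
    if (length(sys_idx) > 0 && sys_idx[1] <= n)
      systole[sys_idx[sys_idx <= n & sys_idx >= 1]] <- TRUE
  }

  amb_sd <- 10^(simcfg$ambient_noise_db / 20)
  ambient <- stats::rnorm(n, sd = amb_sd)

  if (murmur_present) {
    snr <- snr_db %||% simcfg$murmur_snr_db
    band <- simcfg$murmur_band_hz
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    raw <- signal::filtfilt(bf, stats::rnorm(n))
    # ambient power that falls inside the murmur band (flat spectrum)
    amb_band_pow <- amb_sd^2 * (band[2] - band[1]) / (fs / 2)
    target_pow <- amb_band_pow * 10^(snr / 10)
    raw_pow <- mean(raw[systole]^2)
    if (raw_pow > 0) {
      murmur <- raw * sqrt(target_pow / raw_pow)
      x[systole] <- x[systole] + murmur[systole]
    }
  }

  x <- x + ambient
  m <- max(abs(x))
  if (m > 0) x <- x / m
  rec <- pcg_recording(x, fs, location)
  attr(rec, "systole_mask") <- systole
  rec
}

#' Draw one synthetic patient
#'
#' Labels come from the configured murmur prevalence and outcome
#' conditionals; demographics from the configured age distribution with
#' joint age/height/weight missingness. With `simulate_audio = TRUE` the
#' per-location recordings are generated as well ("Present" murmurs at the
#' configured SNR, "Unknown" at the penalised SNR, "Absent" without a
#' murmur).
#'
#' @param cohortcfg A [cohort_config()].
#' @param simcfg A [sim_config()] (required when simulating audio).
#' @param patient_id Identifier for the record.
#' @param simulate_audio Generate waveforms (default TRUE); FALSE draws
#'   labels/demographics only, for distribution checks.
#' @return List with `record` (a [patient_record()]; `recordings$file`
#'   holds the conventional file names) and `recordings` (list of
#'   [pcg_recording()], empty if audio skipped).
#' @export
sample_patient <- function(cohortcfg, simcfg = NULL, patient_id = "P0001",
                           simulate_audio = TRUE) {
  stopifnot(inherits(cohortcfg, "cohort_config"))
  murmur <- sample(names(cohortcfg$murmur_prev), 1,
                   prob = cohortcfg$murmur_prev)
  p_abn <- cohortcfg$p_abnormal_given[[murmur]]
  outcome <- if (stats::runif(1) < p_abn) "Abnormal" else "Normal"
  age <- sample(names(cohortcfg$age_freq), 1, prob = cohortcfg$age_freq)
  sex <- sample(c("Female", "Male"), 1)
  if (age %in% names(.ANTHRO)) {
    a <- .ANTHRO[[age]]
    height <- max(30, stats::rnorm(1, a["h"], a["hs"]))
    weight <- max(1, stats::rnorm(1, a["w"], a["ws"]))
  } else {
    height <- NA_real_; weight <- NA_real_
  }
  pregnant <- if (age == "Adolescent" && sex == "Female")
    stats::runif(1) < 0.05 else FALSE
  if (stats::runif(1) < cohortcfg$missing_rate) {
    age <- "Missing"; height <- NA_real_; weight <- NA_real_
  }

  n_loc <- sample(seq(cohortcfg$n_locations_range[1],
                      cohortcfg$n_locations_range[2]), 1)
  locs <- sample(c("AV", "PV", "TV", "MV"), n_loc, replace = n_loc > 4)
  files <- sprintf("%s_%s_%d.wav", patient_id, locs, seq_len(n_loc))

  recordings <- list()
  if (simulate_audio) {
    stopifnot(inherits(simcfg, "sim_config"))
    snr <- switch(murmur,
                  Present = simcfg$murmur_snr_db,
                  Unknown = simcfg$murmur_snr_db -
                    simcfg$unknown_snr_penalty_db,
                  Absent = NA_real_)
    recordings <- lapply(locs, function(lc) {
      simulate_recording(simcfg, murmur_present = murmur != "Absent",
                         location = lc, snr_db = snr)
    })
  }

  record <- patient_record(
    patient_id = patient_id, age_group = age, sex = sex,
    height_cm = height, weight_kg = weight, pregnant = pregnant,
    murmur = murmur, outcome = outcome,
    recordings = data.frame(location = locs, file = files,
                            stringsAsFactors = FALSE))
  list(record = record, recordings = recordings)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one text header and the per-location WAVs per patient in the
#' key:value header dialect, plus a `manifest.json` recording the seed and
#' configurations. [scan_dataset()] on the output round-trips every label
#' exactly (numeric demographics are written at 0.1 precision).
#' Byte-identical trees for identical seeds.
#'
#' @param cohortcfg A [cohort_config()].
#' @param simcfg A [sim_config()].
#' @param outdir Output directory (must be empty or absent unless `force`).
#' @param seed Cohort seed.
#' @param force Overwrite a non-empty directory.
#' @return The scanned `dataset_catalog` (schema `"synthetic"`), invisibly.
#' @export
generate_cohort <- function(cohortcfg, simcfg, outdir, seed = 1L,
                            force = FALSE) {
  stopifnot(inherits(cohortcfg, "cohort_config"),
            inherits(simcfg, "sim_config"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop("output directory is not empty: ", outdir, " (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  width <- max(4L, nchar(as.character(cohortcfg$n_patients)))
  for (i in seq_len(cohortcfg$n_patients)) {
    pid <- sprintf(paste0("P%0", width, "d"), i)
    sp <- sample_patient(cohortcfg, simcfg, pid, simulate_audio = TRUE)
    rec <- sp$record
    for (j in seq_along(sp$recordings)) {
      write_wav(sp$recordings[[j]]$samples, simcfg$fs_hz,
                file.path(outdir, rec$recordings$file[j]))
    }
    header <- c(
      sprintf("%s %d %d", pid, nrow(rec$recordings), simcfg$fs_hz),
      sprintf("%s %s", rec$recordings$location, rec$recordings$file),
      sprintf("#Age: %s", if (rec$age_group == "Missing") "NA" else rec$age_group),
      sprintf("#Sex: %s", rec$sex),
      sprintf("#Height: %s", if (is.na(rec$height_cm)) "NA"
              else sprintf("%.1f", rec$height_cm)),
      sprintf("#Weight: %s", if (is.na(rec$weight_kg)) "NA"
              else sprintf("%.1f", rec$weight_kg)),
      sprintf("#Pregnancy status: %s", if (is.na(rec$pregnant)) "NA"
              else if (rec$pregnant) "True" else "False"),
      sprintf("#Murmur: %s", rec$murmur),
      sprintf("#Outcome: %s", rec$outcome))
    writeLines(header, file.path(outdir, paste0(pid, ".txt")))
  }
  jsonlite::write_json(
    list(seed = seed, n_patients = cohortcfg$n_patients,
         sim_config = unclass(simcfg), cohort_config = unclass(cohortcfg)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(scan_dataset(outdir, schema = "synthetic"))
}
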