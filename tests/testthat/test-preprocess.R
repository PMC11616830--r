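test_that("resampling preserves duration and tone frequency", {
  r <- pcg_recording(sin(2 * pi * 100 * (0:7999) / 2000), 2000)
  up <- resample_recording(r, 4000)
  expect_length(up$samples, 16000)
  expect_equal(up$fs_hz, 4000L)

  # FFT-peak oracle: the dominant bin stays at 100 Hz after upsampling
  spec <- Mod(stats::fft(up$samples))
  half <- seq_len(8000)
  peak_hz <- (which.max(spec[half + 1])) * 4000 / 16000
  expect_equal(peak_hz, 100, tolerance = 1e-6)

  # identity when rates match
  same <- resample_recording(r, 2000)
  expect_identical(same$samples, r$samples)
  expect_error(resample_recording(r, 0), "positive")
})

test_that("amplitude normalisation divides by the peak and flags silence", {
  expect_equal(as.numeric(normalize_amplitude(c(2, -4, 1))),
               c(0.5, -1, 0.25))
  y <- normalize_amplitude(c(0.5, -1, 0.25))
  expect_equal(as.numeric(y), c(0.5, -1, 0.25))  # idempotent
  z <- normalize_amplitude(numeric(5))
  expect_true(attr(z, "degenerate"))
  expect_equal(as.numeric(z), numeric(5))
})

test_that("window counts follow the closed form and match brute-force enumeration", {
  p <- desk_params()
  expect_length(segment_windows(numeric(5 * 4000), 4000, p), 2)
  expect_length(segment_windows(numeric(80 * 4000), 4000, p), 77)
  short <- segment_windows(numeric(round(3.2 * 4000)), 4000, p)
  expect_length(short, 1)
  expect_true(short[[1]]$short)
  expect_length(short[[1]]$samples, 16000)

  # offsets are 0, 1, 2, ... seconds
  segs <- segment_windows(numeric(7 * 4000), 4000, p)
  expect_equal(vapply(segs, `[[`, 0, "offset_s"), 0:3)

  # brute-force oracle over random durations and strides
  set.seed(99)
  fs <- 100  # coarse rate keeps the enumeration cheap
  for (i in 1:1000) {
    dur <- stats::runif(1, 4, 90)
    stride <- sample(1:3, 1)
    pp <- spectrogram_params(stride_s = stride, target_fs_hz = fs,
                             fmax_hz = 50, n_mels = 4)
    n <- round(dur * fs)
    # enumerate valid 4 s offsets directly
    expected <- 0L; start <- 0L
    while (start + 4 * fs <= n) {
      expected <- expected + 1L
      start <- start + stride * fs
    }
    got <- length(segment_windows(numeric(n), fs, pp))
    expect_equal(got, max(expected, 1L))
  }
})

test_that("log-mel windows have the derived frame count and stable geometry", {
  p <- desk_params()
  w <- log_mel(stats::rnorm(16000), 4000, p)
  # 1 + floor((16000 - 100) / 40) = 398 frames under no centering
  expect_equal(dim(w$image), c(32, 398))
  expect_equal(n_stft_frames(p), 398L)
  expect_equal(n_stft_frames(spectrogram_params()), 398L)
  expect_true(all(is.finite(w$image)))

  # exhaustive frame enumeration oracle for several rates
  for (fs in c(2000L, 4000L, 8000L)) {
    pp <- spectrogram_params(target_fs_hz = fs, fmax_hz = fs / 2, n_mels = 8)
    win <- round(25 * fs / 1000); hop <- round(10 * fs / 1000)
    count <- 0L; start <- 1L
    while (start + win - 1L <= 4 * fs) {
      count <- count + 1L
      start <- start + hop
    }
    expect_equal(n_stft_frames(pp), count)
  }

  # a segment of the wrong length is rejected
  expect_error(log_mel(stats::rnorm(1000), 4000, p), "exactly")
})

test_that("log-mel responds to frequency content and is shift-equivariant in amplitude", {
  p <- spectrogram_params(n_mels = 32, scale_01 = FALSE)
  # silent segment: constant image at the log floor
  silent <- log_mel(numeric(16000), 4000, p)
  expect_equal(max(silent$image) - min(silent$image), 0)
  expect_equal(unique(as.vector(silent$image)), 10 * log10(p$log_floor))

  # band-limited noise: higher-frequency band excites higher mel bands
  bf1 <- signal::butter(4, c(250, 350) / 2000, "pass")
  bf2 <- signal::butter(4, c(1400, 1600) / 2000, "pass")
  set.seed(5)
  x <- stats::rnorm(16000)
  lo <- log_mel(signal::filtfilt(bf1, x), 4000, p)
  hi <- log_mel(signal::filtfilt(bf2, x), 4000, p)
  band_of <- function(w) which.max(rowMeans(w$image))
  expect_gt(band_of(hi), band_of(lo))
  # mel centre frequency oracle: the argmax band brackets the input band
  centres <- attr(mel_filterbank(32, 128, 4000, 10, 2000), "centre_freqs_hz")
  expect_gt(centres[band_of(hi)], 1000)
  expect_lt(centres[band_of(lo)], 600)

  # scaling the waveform shifts the (unscaled) log image by a constant
  base <- log_mel(x, 4000, p)
  scaled <- log_mel(3 * x, 4000, p)
  diff <- scaled$image - base$image
  expect_lt(max(diff) - min(diff), 1e-8)
  expect_equal(mean(diff), 20 * log10(3), tolerance = 1e-6)

  # deterministic: identical calls give identical images
  expect_identical(log_mel(x, 4000, p)$image, base$image)
})

test_that("mel filterbank centre frequencies are increasing and bounded", {
  fb <- mel_filterbank(32, 128, 4000, 10, 2000)
  centres <- attr(fb, "centre_freqs_hz")
  expect_length(centres, 32)
  expect_true(all(diff(centres) > 0))
  expect_true(all(centres >= 10 & centres <= 2000))
  expect_equal(dim(fb), c(32, 65))
  expect_error(log_mel(stats::rnorm(8000), 2000, desk_params()),
               "sampling rate")
})

test_that("catalog preprocessing is reproducible and excludes unusable patients", {
  dir <- withr::local_tempdir()
  ct <- make_cohort(n = 6, seed = 41, dir = dir)
  ws1 <- preprocess_catalog(ct, desk_params())
  ws2 <- preprocess_catalog(ct, desk_params())
  expect_identical(ws1$images, ws2$images)
  expect_identical(ws1$meta, ws2$meta)
  expect_equal(dim(ws1$images)[1:2], c(32, 398))
  expect_setequal(unique(ws1$meta$patient_id), names(ct$patients))

  # a patient with zero recordings is excluded with a warning
  ct$patients[["PXXXX"]] <- patient_record("PXXXX", murmur = "Absent",
                                           outcome = "Normal")
  expect_warning(ws3 <- preprocess_catalog(ct, desk_params()), "excluded")
  expect_equal(ws3$excluded, "PXXXX")
})
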