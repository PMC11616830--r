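# Waveform -> overlapping log-mel spectrogram windows.
#
# Defaults follow the screening pipeline's preprocessing: 4 s segments with a
# 1 s stride, STFT with a periodic Hann window of 25 ms and a 10 ms hop,
# mel filterbank spanning 10-2000 Hz, log-compressed power. STFT centering is
# off, so the frame count has the closed form
#   n_frames = 1 + floor((n_samples - win) / hop).

#' Spectrogram parameter set
#'
#' @param window_s Segment length in seconds (default 4).
#' @param stride_s Segment hop in seconds (default 1).
#' @param stft_window_ms STFT analysis window in milliseconds (default 25,
#'   periodic Hann).
#' @param stft_hop_ms STFT hop in milliseconds (default 10).
#' @param fmin_hz,fmax_hz Mel filterbank frequency range (defaults 10 and
#'   2000 Hz; `fmax_hz` must not exceed Nyquist).
#' @param n_mels Number of mel bands (default 128; the source pipeline does
#'   not pin this down, 128 is the usual audio-classification resolution).
#' @param log_floor Power floor before taking logs (default 1e-10).
#' @param target_fs_hz Sampling rate all audio is brought to before
#'   spectrogram extraction (default 4000 Hz).
#' @param scale_01 Min-max scale each log-mel window to `[0, 1]`
#'   (default TRUE; the network input convention).
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_s = 4, stride_s = 1,
                               stft_window_ms = 25, stft_hop_ms = 10,
                               fmin_hz = 10, fmax_hz = 2000, n_mels = 128,
                               log_floor = 1e-10, target_fs_hz = 4000,
                               scale_01 = TRUE) {
  p <- list(window_s = window_s, stride_s = stride_s,
            stft_window_ms = stft_window_ms, stft_hop_ms = stft_hop_ms,
            fmin_hz = fmin_hz, fmax_hz = fmax_hz, n_mels = as.integer(n_mels),
            log_floor = log_floor, target_fs_hz = as.integer(target_fs_hz),
            scale_01 = isTRUE(scale_01))
  stopifnot(p$fmin_hz < p$fmax_hz, p$fmax_hz <= p$target_fs_hz / 2,
            p$stft_hop_ms <= p$stft_window_ms,
            p$window_s * 1000 >= p$stft_window_ms,
            p$n_mels >= 1, p$log_floor > 0, p$stride_s > 0)
  class(p) <- "spectrogram_params"
  p
}

#' Resample a recording to a target rate
#'
#' Polyphase FIR resampling (via [signal::resample()]); a no-op when the
#' rates already match. Output duration matches input duration to within one
#' sample.
#'
#' @param recording A [pcg_recording()].
#' @param target_fs Target rate in Hz.
#' @return A resampled [pcg_recording()].
#' @export
resample_recording <- function(recording, target_fs) {
  stopifnot(inherits(recording, "pcg_recording"))
  target_fs <- as.integer(target_fs)
  if (is.na(target_fs) || target_fs <= 0) stop("target_fs must be positive")
  if (target_fs == recording$fs_hz) return(recording)
  g <- .gcd(target_fs, recording$fs_hz)
  y <- signal::resample(recording$samples, p = target_fs %/% g,
                        q = recording$fs_hz %/% g)
  n_expect <- round(length(recording$samples) * target_fs / recording$fs_hz)
  if (length(y) > n_expect) y <- y[seq_len(n_expect)]
  if (length(y) < n_expect) y <- c(y, rep(0, n_expect - length(y)))
  pcg_recording(y, target_fs, recording$location)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Peak-normalise an amplitude vector to [-1, 1]
#'
#' Divides by the maximum absolute value; idempotent. An all-zero signal is
#' returned unchanged with attribute `degenerate = TRUE`.
#'
#' @param samples Finite numeric vector.
#' @return Normalised vector; attribute `degenerate` flags all-zero input.
#' @export
normalize_amplitude <- function(samples) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  m <- max(abs(samples))
  if (m == 0) {
    attr(samples, "degenerate") <- TRUE
    return(samples)
  }
  out <- samples / m
  attr(out, "degenerate") <- FALSE
  out
}

#' Cut a signal into overlapping fixed-length segments
#'
#' For a signal of duration `D` >= `window_s`, yields
#' `floor((D - window_s) / stride_s) + 1` segments at offsets 0, `stride_s`,
#' 2 `stride_s`, ... seconds, each exactly `window_s * fs` samples. Shorter
#' signals yield a single zero-padded segment flagged `short = TRUE`
#' (discarding them would silently drop patients whose records are under 4 s).
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param params A [spectrogram_params()].
#' @return List of segments; each has elements `samples`, `offset_s`, `short`.
#' @export
segment_windows <- function(samples, fs, params = spectrogram_params()) {
  stopifnot(inherits(params, "spectrogram_params"))
  n_win <- as.integer(round(params$window_s * fs))
  n_hop <- as.integer(round(params$stride_s * fs))
  n <- length(samples)
  if (n < n_win) {
    return(list(list(samples = c(samples, rep(0, n_win - n)),
                     offset_s = 0, short = TRUE)))
  }
  starts <- seq.int(1L, n - n_win + 1L, by = n_hop)
  lapply(starts, function(s) {
    list(samples = samples[s:(s + n_win - 1L)],
         offset_s = (s - 1L) / fs, short = FALSE)
  })
}

#' Mel filterbank matrix
#'
#' Triangular filters on the HTK mel scale (`mel = 2595 log10(1 + f/700)`),
#' centre frequencies strictly increasing within `[fmin, fmax]`.
#'
#' @param n_mels Number of bands.
#' @param n_fft FFT length.
#' @param fs Sampling rate (Hz).
#' @param fmin,fmax Band edge frequencies (Hz).
#' @return `n_mels` x `(n_fft/2 + 1)` matrix, with attribute
#'   `centre_freqs_hz`.
#' @export
mel_filterbank <- function(n_mels, n_fft, fs, fmin, fmax) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2 + 1
  fft_freqs <- (seq_len(n_bins) - 1) * fs / n_fft
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (fft_freqs - lo) / (ce - lo)
    dn <- (hi - fft_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  attr(fb, "centre_freqs_hz") <- hz_pts[2:(n_mels + 1)]
  fb
}

# Internal: periodic Hann window of length n.
.hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Internal: framed STFT power spectrum, no centering.
# Returns (n_fft/2+1) x n_frames matrix plus frequency axis.
.stft_power <- function(samples, fs, window_ms, hop_ms) {
  win <- as.integer(round(window_ms * fs / 1000))
  hop <- as.integer(round(hop_ms * fs / 1000))
  n <- length(samples)
  if (n < win) stop("signal shorter than one STFT window")
  n_frames <- 1L + (n - win) %/% hop
  n_fft <- 2^ceiling(log2(win))
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  frames <- matrix(samples[idx], nrow = win) * .hann_periodic(win)
  if (n_fft > win)
    frames <- rbind(frames, matrix(0, n_fft - win, n_frames))
  spec <- stats::mvfft(frames)[seq_len(n_fft %/% 2 + 1), , drop = FALSE]
  list(power = Mod(spec)^2, freqs = (seq_len(n_fft %/% 2 + 1) - 1) * fs / n_fft,
       n_frames = n_frames, n_fft = n_fft)
}

#' Log-mel spectrogram of one fixed-length segment
#'
#' STFT power (periodic Hann, no centering, FFT length = next power of two
#' above the window length), mel filterbank, then `10 log10(max(power,
#' log_floor))`. When `params$scale_01` is set the image is min-max scaled
#' to `[0, 1]` per window (constant images map to 0).
#'
#' @param segment Numeric vector of exactly `window_s * fs` samples (as
#'   produced by [segment_windows()]).
#' @param fs Sampling rate; must equal `params$target_fs_hz`.
#' @param params A [spectrogram_params()].
#' @param patient_id,recording_index,offset_s Provenance fields attached to
#'   the result.
#' @return Object of class `spectrogram_window`: list with `image`
#'   (`n_mels` x `n_frames` matrix), `patient_id`, `recording_index`,
#'   `offset_s`.
#' @export
log_mel <- function(segment, fs, params = spectrogram_params(),
                    patient_id = NA_character_, recording_index = NA_integer_,
                    offset_s = NA_real_) {
  stopifnot(inherits(params, "spectrogram_params"))
  if (fs != params$target_fs_hz)
    stop("segment sampling rate ", fs, " != target ", params$target_fs_hz)
  if (params$fmax_hz > fs / 2) stop("fmax exceeds Nyquist frequency")
  n_expect <- as.integer(round(params$window_s * fs))
  if (length(segment) != n_expect)
    stop("segment must have exactly ", n_expect, " samples")
  st <- .stft_power(segment, fs, params$stft_window_ms, params$stft_hop_ms)
  fb <- .mel_fb_cached(params$n_mels, st$n_fft, fs,
                       params$fmin_hz, params$fmax_hz)
  mel_power <- fb %*% st$power
  img <- 10 * log10(pmax(mel_power, params$log_floor))
  if (params$scale_01) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  }
  structure(list(image = img, patient_id = patient_id,
                 recording_index = recording_index, offset_s = offset_s),
            class = "spectrogram_window")
}

# Filterbanks are small; memoise per geometry within a session.
.mel_cache <- new.env(parent = emptyenv())
.mel_fb_cached <- function(n_mels, n_fft, fs, fmin, fmax) {
  key <- paste(n_mels, n_fft, fs, fmin, fmax, sep = "_")
  if (is.null(.mel_cache[[key]]))
    .mel_cache[[key]] <- mel_filterbank(n_mels, n_fft, fs, fmin, fmax)
  .mel_cache[[key]]
}

#' Number of STFT frames for a segment under these parameters
#' @param params A [spectrogram_params()].
#' @return Integer frame count (e.g. 398 for 4 s at 4000 Hz with a 25 ms
#'   window and 10 ms hop).
#' @export
n_stft_frames <- function(params = spectrogram_params()) {
  fs <- params$target_fs_hz
  n <- as.integer(round(params$window_s * fs))
  win <- as.integer(round(params$stft_window_ms * fs / 1000))
  hop <- as.integer(round(params$stft_hop_ms * fs / 1000))
  1L + (n - win) %/% hop
}

#' Preprocess one recording into spectrogram windows
#'
#' Resamples to the target rate, peak-normalises per recording, segments
#' into overlapping windows, and computes the log-mel image of each.
#'
#' @param recording A [pcg_recording()].
#' @param params A [spectrogram_params()].
#' @param patient_id,recording_index Provenance.
#' @return List of `spectrogram_window` objects.
#' @export
preprocess_recording <- function(recording, params = spectrogram_params(),
                                 patient_id = NA_character_,
                                 recording_index = 1L) {
  rec <- resample_recording(recording, params$target_fs_hz)
  x <- as.numeric(normalize_amplitude(rec$samples))
  segs <- segment_windows(x, rec$fs_hz, params)
  lapply(segs, function(s) {
    log_mel(s$samples, rec$fs_hz, params, patient_id = patient_id,
            recording_index = recording_index, offset_s = s$offset_s)
  })
}

#' Preprocess a whole catalog into a window set
#'
#' Reads every recording of every patient, produces all spectrogram windows,
#' and stacks them into one array. Patients with zero usable recordings are
#' excluded with a warning (their ids are reported in the result).
#'
#' @param catalog A `dataset_catalog`.
#' @param params A [spectrogram_params()].
#' @param task Label task attached per window (`"murmur_binary"` or
#'   `"outcome_binary"`).
#' @param positive_murmur Murmur labels counted positive (default
#'   Present and Unknown).
#' @param require_labels Drop patients whose task label is missing
#'   (default TRUE, the training convention); set FALSE for prediction on
#'   unlabelled data.
#' @return List of class `window_set`: `images` array
#'   (`n_mels` x `n_frames` x `n_windows`), `meta` data frame
#'   (`patient_id`, `recording_index`, `offset_s`, `label`), `params`,
#'   `excluded` (ids skipped for having no recordings or missing labels).
#' @export
preprocess_catalog <- function(catalog, params = spectrogram_params(),
                               task = "murmur_binary",
                               positive_murmur = c("Present", "Unknown"),
                               require_labels = TRUE) {
  labels <- catalog_labels(catalog, task, positive_murmur)
  imgs <- list(); meta <- list(); excluded <- character()
  for (pid in names(catalog$patients)) {
    p <- catalog$patients[[pid]]
    if (nrow(p$recordings) == 0 ||
        (require_labels && is.na(labels[[pid]]))) {
      excluded <- c(excluded, pid)
      next
    }
    recs <- patient_recordings(catalog, p)
    for (ri in seq_along(recs)) {
      wins <- preprocess_recording(recs[[ri]], params, pid, ri)
      for (w in wins) {
        imgs[[length(imgs) + 1L]] <- w$image
        meta[[length(meta) + 1L]] <- data.frame(
          patient_id = pid, recording_index = ri, offset_s = w$offset_s,
          label = labels[[pid]], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(excluded) > 0)
    warning("excluded ", length(excluded),
            " patient(s) with no usable recordings or missing labels")
  if (length(imgs) == 0) stop("catalog produced no spectrogram windows")
  arr <- array(unlist(imgs),
               dim = c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
  structure(list(images = arr, meta = do.call(rbind, meta),
                 params = params, excluded = excluded),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d from %d patients\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              length(unique(x$meta$patient_id))))
  invisible(x)
}
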