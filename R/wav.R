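#' Read a RIFF PCM WAV file
#'
#' Minimal reader for the uncompressed PCM WAV files used by
#' phonocardiogram datasets (16-bit little-endian is the common case;
#' 8/24/32-bit integer and 32/64-bit float PCM are also handled).
#' Multi-channel audio is collapsed to mono by the channel mean.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector scaled to `[-1, 1]` by the
#'   sample-format full scale), `fs_hz` (sampling rate), and `n_channels`
#'   (channel count of the container before the mono collapse).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        fs_hz        = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0) {
    stop("WAV file has no audio samples: ", path)
  }

  x <- .decode_pcm(data_raw, fmt$audio_format, fmt$bits, path)
  nch <- max(1L, fmt$n_channels)
  if (nch > 1L) {
    usable <- (length(x) %/% nch) * nch
    x <- colMeans(matrix(x[seq_len(usable)], nrow = nch))
  }
  if (length(x) == 0) stop("WAV file decodes to zero samples: ", path)
  list(samples = x, fs_hz = as.integer(fmt$fs_hz), n_channels = nch)
}

.decode_pcm <- function(raw, audio_format, bits, path) {
  if (audio_format == 3L) { # IEEE float
    if (bits == 32) return(readBin(raw, "numeric", length(raw) / 4, 4, endian = "little"))
    if (bits == 64) return(readBin(raw, "numeric", length(raw) / 8, 8, endian = "little"))
    stop("unsupported float WAV bit depth ", bits, ": ", path)
  }
  if (audio_format != 1L) stop("unsupported WAV audio format ", audio_format, ": ", path)
  if (bits == 16) {
    return(readBin(raw, "integer", length(raw) / 2, 2, signed = TRUE,
                   endian = "little") / 32768)
  }
  if (bits == 8) { # unsigned
    return((as.integer(raw) - 128) / 128)
  }
  if (bits == 32) {
    return(readBin(raw, "integer", length(raw) / 4, 4, endian = "little") / 2147483648)
  }
  if (bits == 24) {
    n <- length(raw) %/% 3
    b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    return(v / 8388608)
  }
  stop("unsupported PCM WAV bit depth ", bits, ": ", path)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param fs_hz Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs_hz, path) {
  stopifnot(is.numeric(samples), length(samples) >= 1, fs_hz >= 1)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(fs_hz), con, 4, endian = "little")
  writeBin(as.integer(fs_hz * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")              # block align
  writeBin(16L, con, 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
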