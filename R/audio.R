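#' Mono audio segment
#'
#' Lightweight container for a mono waveform: samples in \[-1, 1\], a sample
#' rate in Hz, and the absolute start time (seconds from the beginning of the
#' recording) of the first sample.
#'
#' @param samples Numeric vector of samples in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Absolute start time in seconds (default 0).
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0) {
    stopf("sample_rate must be a single positive number, got %s", format(sample_rate)[1])
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stopf("samples exceed full scale (max |x| = %.4f > 1)", max(abs(samples)))
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf(
    "<audio_segment: %d samples @ %g Hz (%.3f s), start %.3f s>\n",
    length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate, x$start_time
  ))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param audio An `audio_segment`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$sample_rate

#' Read a WAV file
#'
#' Reads mono (or, optionally downmixed, stereo) PCM 16-bit or IEEE float32
#' RIFF/WAVE files.
#'
#' @param path Path to a `.wav` file.
#' @param downmix If `TRUE`, multichannel input is averaged to mono; if
#'   `FALSE` (default) multichannel input is rejected.
#' @return An [audio_segment()].
#' @export
read_wav <- function(path, downmix = FALSE) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 44) stopf("not a WAV file (too short): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("malformed WAV (data before fmt): %s", path)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", len %/% 2L, 2L, signed = TRUE, endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", len %/% 4L, 4L, endian = "little")
      } else {
        stopf("unsupported WAV encoding (format %d, %d bit): %s", fmt$audio_format, fmt$bits, path)
      }
    } else {
      seek(con, len + len %% 2L, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples) || length(samples) == 0L) stopf("WAV contains no audio data: %s", path)

  if (fmt$n_channels > 1L) {
    if (!downmix) stopf("multichannel WAV (%d channels); pass downmix = TRUE", fmt$n_channels)
    m <- matrix(samples, nrow = fmt$n_channels)
    samples <- colMeans(m)
  }
  audio_segment(pmin(1, pmax(-1, samples)), fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param path Output path.
#' @param audio An [audio_segment()].
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, audio, bits = 16L) {
  stopifnot(inherits(audio, "audio_segment"))
  if (!bits %in% c(16L, 32L)) stopf("bits must be 16 or 32")
  n <- length(audio$samples)
  bytes_per <- bits %/% 8L
  data_len <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")  # mono
  sr <- as.integer(round(audio$sample_rate))
  writeBin(sr, con, 4L, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, 4L, endian = "little")  # byte rate
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")       # block align
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, 4L, endian = "little")
  x <- pmin(1, pmax(-1, audio$samples))
  if (bits == 16L) {
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(x, con, 4L, endian = "little")
  }
  invisible(path)
}
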