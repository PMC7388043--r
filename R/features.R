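# Time-frequency features: log-Mel spectrograms of 650 ms windows for the
# CNN, and the MFCC / delta-MFCC / delta-ZCR matrix for sex assignment.

#' Feature configuration for the CNN input representation
#'
#' Defaults are pinned so that a 650 ms window at 22,050 Hz yields exactly an
#' 80 x 122 log-Mel spectrogram, matching the network's first feature map:
#' window 14,333 samples, STFT frame 1024, hop 110, 80 Mel bands, no center
#' padding; a trailing partial frame is zero-padded, so the frame count is
#' `1 + ceiling((window_samples - frame_length) / hop)` = 122.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param window_duration Analysis window duration in seconds (default 0.650).
#' @param frame_length STFT frame length in samples.
#' @param hop STFT hop in samples.
#' @param n_mels Number of Mel bands.
#' @param log_floor Log floor in dB (values never fall below this).
#' @param fmin,fmax Filterbank frequency range in Hz (`fmax` defaults to
#'   Nyquist).
#' @return A `feature_config` list with derived fields `window_samples` and
#'   `n_frames`.
#' @export
feature_config <- function(sample_rate = 22050, window_duration = 0.650,
                           frame_length = 1024L, hop = 110L, n_mels = 80L,
                           log_floor = -100, fmin = 0, fmax = NULL) {
  # half-up rounding: 0.650 s at 22050 Hz gives 14333 samples, hence 122 frames
  window_samples <- floor(window_duration * sample_rate + 0.5)
  # trailing partial frame is zero-padded: 14333 samples -> exactly 122 frames
  n_frames <- 1L + as.integer(ceiling((window_samples - frame_length) / hop))
  if (is.null(fmax)) fmax <- sample_rate / 2
  structure(list(
    sample_rate = sample_rate, window_duration = window_duration,
    frame_length = as.integer(frame_length), hop = as.integer(hop),
    n_mels = as.integer(n_mels), log_floor = log_floor,
    fmin = fmin, fmax = fmax,
    window_samples = as.integer(window_samples), n_frames = as.integer(n_frames)
  ), class = "feature_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular Mel filterbank: n_mels x (n_fft/2 + 1)
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0, fmax = sample_rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (0:(n_bins - 1L)) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# power STFT: (n_fft/2 + 1) x n_frames, Hann window, no centering.
# pad_end = TRUE zero-pads a trailing partial frame (frame count
# 1 + ceiling((n - L)/hop)); FALSE drops it (1 + floor((n - L)/hop)).
stft_power <- function(x, frame_length, hop, n_fft = frame_length, pad_end = FALSE) {
  n <- length(x)
  if (n < frame_length) stopf("signal shorter than one frame (%d < %d samples)", n, frame_length)
  if (pad_end) {
    n_frames <- 1L + as.integer(ceiling((n - frame_length) / hop))
    need <- frame_length + (n_frames - 1L) * hop
    if (need > n) x <- c(x, numeric(need - n))
  } else {
    n_frames <- 1L + (n - frame_length) %/% hop
  }
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame_length - 1L)) / frame_length)
  idx <- outer(0:(frame_length - 1L), (0:(n_frames - 1L)) * hop, `+`) + 1L
  frames <- matrix(x[idx], frame_length, n_frames) * win
  if (n_fft > frame_length) {
    frames <- rbind(frames, matrix(0, n_fft - frame_length, n_frames))
  }
  sp <- stats::mvfft(frames)
  Mod(sp[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])^2
}

#' Log-Mel spectrogram of one fixed-length window
#'
#' Pure and deterministic. Windows shorter than the configured duration are
#' symmetrically zero-padded; longer windows are rejected (the caller must
#' window first).
#'
#' @param window An [audio_segment()] no longer than
#'   `config$window_duration`.
#' @param config A [feature_config()].
#' @param log Return log-compressed values (dB, floored at
#'   `config$log_floor`); set `FALSE` for raw Mel power.
#' @return A `mel_spectrogram`: an `n_mels x n_frames` matrix with the config
#'   attached as attribute `config`.
#' @export
mel_spectrogram <- function(window, config = feature_config(), log = TRUE) {
  stopifnot(inherits(window, "audio_segment"))
  if (window$sample_rate != config$sample_rate) {
    stopf("window sample rate %g != config sample rate %g",
          window$sample_rate, config$sample_rate)
  }
  x <- window$samples
  if (length(x) > config$window_samples) {
    stopf("window of %d samples exceeds configured %d (0.65 s); window first",
          length(x), config$window_samples)
  }
  x <- pad_to_length(x, config$window_samples)
  fb <- cached_filterbank(config)
  p <- stft_power(x, config$frame_length, config$hop, pad_end = TRUE)
  m <- fb %*% p
  if (log) {
    floor_pow <- 10^(config$log_floor / 10)
    m <- 10 * log10(m + floor_pow)
  }
  structure(m, class = c("mel_spectrogram", "matrix"), config = config)
}

# symmetric zero-padding to exactly n samples
pad_to_length <- function(x, n) {
  d <- n - length(x)
  if (d <= 0L) return(x[seq_len(n)])
  left <- d %/% 2L
  c(numeric(left), x, numeric(d - left))
}

.fb_cache <- new.env(parent = emptyenv())
cached_filterbank <- function(config) {
  key <- paste(config$n_mels, config$frame_length, config$sample_rate,
               config$fmin, config$fmax, sep = "|")
  if (is.null(.fb_cache[[key]])) {
    .fb_cache[[key]] <- mel_filterbank(config$n_mels, config$frame_length,
                                       config$sample_rate, config$fmin, config$fmax)
  }
  .fb_cache[[key]]
}

# DCT-II matrix (orthonormal), n_out x n_in
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  n <- 0:(n_in - 1L)
  m <- sqrt(2 / n_in) * cos(outer(k, (n + 0.5) * pi / n_in))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# centered first difference with edge replication, row-wise over a matrix
delta_rows <- function(m) {
  f <- ncol(m)
  if (f < 2L) stopf("need at least 2 frames for a time derivative")
  prev <- m[, c(1L, seq_len(f - 1L)), drop = FALSE]
  nxt <- m[, c(seq.int(2L, f), f), drop = FALSE]
  (nxt - prev) / 2
}

#' MFCC / delta-MFCC / delta-ZCR features for sex assignment
#'
#' Computes 20 Mel-frequency cepstral coefficients per frame (4096-point FFT,
#' 4096-sample frames, hop 256, including coefficient 0), their first
#' time-derivative estimates (centered difference, edge replication), and the
#' first time-derivative of the per-frame zero-crossing rate, vertically
#' concatenated into a 41 x F matrix (F = 1 + floor((N - 4096)/256) frames
#' for an N-sample signal).
#'
#' @param signal An [audio_segment()] of at least 4096 samples.
#' @param n_mfcc Number of cepstral coefficients (default 20).
#' @param frame_length Analysis frame length in samples (default 4096).
#' @param hop Samples between successive frames (default 256).
#' @param n_mels Mel bands used before the cepstral transform (default 40).
#' @return A `sex_features` matrix with `2 * n_mfcc + 1` rows and F columns.
#' @export
extract_sex_features <- function(signal, n_mfcc = 20L, frame_length = 4096L,
                                 hop = 256L, n_mels = 40L) {
  stopifnot(inherits(signal, "audio_segment"))
  x <- signal$samples
  n <- length(x)
  if (n < frame_length) {
    stopf("signal of %d samples shorter than one %d-sample frame", n, frame_length)
  }
  sr <- signal$sample_rate
  p <- stft_power(x, frame_length, hop)
  fb <- mel_filterbank(n_mels, frame_length, sr)
  logmel <- log(fb %*% p + 1e-10)
  mfcc <- dct_matrix(n_mfcc, n_mels) %*% logmel

  n_frames <- ncol(p)
  starts <- (0:(n_frames - 1L)) * hop
  sgn <- ifelse(x >= 0, 1, -1)
  changes <- c(0, abs(diff(sgn)) / 2)        # 1 at every sign change
  cum <- cumsum(changes)
  zcr <- (cum[starts + frame_length] - cum[starts + 1L]) / (frame_length - 1L)

  out <- rbind(mfcc, delta_rows(mfcc), delta_rows(matrix(zcr, 1L)))
  rownames(out) <- c(paste0("mfcc", seq_len(n_mfcc) - 1L),
                     paste0("dmfcc", seq_len(n_mfcc) - 1L), "dzcr")
  structure(out, class = c("sex_features", "matrix"))
}
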