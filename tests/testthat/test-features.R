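test_that("feature_config derives the pinned window geometry", {
  fc <- feature_config()
  expect_equal(fc$window_samples, 14333L)
  expect_equal(fc$n_frames, 122L)
  expect_equal(fc$n_mels, 80L)
})

test_that("STFT power matches a direct DFT computation", {
  set.seed(4)
  x <- rnorm(700)
  L <- 256L; hop <- 100L
  p <- nightcough:::stft_power(x, L, hop)
  n_frames <- 1L + (length(x) - L) %/% hop
  expect_equal(dim(p), c(L %/% 2L + 1L, n_frames))
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  for (f in seq_len(n_frames)) {
    frame <- x[(f - 1L) * hop + seq_len(L)] * win
    expect_equal(p[, f], Mod(fft(frame))[1:(L %/% 2L + 1L)]^2, tolerance = 1e-10)
  }
})

test_that("pad_end zero-pads a trailing partial frame", {
  x <- rnorm(300)
  p <- nightcough:::stft_power(x, 256L, 100L, pad_end = TRUE)
  expect_equal(ncol(p), 1L + as.integer(ceiling((300 - 256) / 100)))
  p2 <- nightcough:::stft_power(c(x, numeric(56)), 256L, 100L)
  expect_equal(p, p2)
})

test_that("mel filterbank triangles are nonnegative and peak once per band", {
  fb <- nightcough:::mel_filterbank(40L, 1024L, 22050)
  expect_equal(dim(fb), c(40L, 513L))
  expect_true(all(fb >= 0))
  expect_true(all(apply(fb, 1, max) > 0))
  # band centers increase monotonically
  centers <- apply(fb, 1, which.max)
  expect_true(all(diff(centers) > 0))
})

test_that("mel_spectrogram yields an 80 x 122 matrix and respects the log floor", {
  fc <- feature_config()
  a <- audio_segment(numeric(fc$window_samples), fc$sample_rate)
  m <- mel_spectrogram(a, fc)
  expect_equal(dim(m), c(80L, 122L))
  expect_true(all(abs(m - fc$log_floor) < 1e-6))
  set.seed(8)
  b <- audio_segment(runif(fc$window_samples, -0.5, 0.5), fc$sample_rate)
  m2 <- mel_spectrogram(b, fc)
  expect_true(all(m2 >= fc$log_floor))
  expect_gt(max(m2), -40)
  # pure and deterministic
  expect_identical(m2, mel_spectrogram(b, fc))
})

test_that("mel_spectrogram pads short windows and rejects long ones", {
  fc <- feature_config()
  short <- audio_segment(runif(5000, -0.1, 0.1), fc$sample_rate)
  expect_equal(dim(mel_spectrogram(short, fc)), c(80L, 122L))
  long <- audio_segment(numeric(fc$window_samples + 1L), fc$sample_rate)
  expect_error(mel_spectrogram(long, fc), "exceeds")
  wrong_sr <- audio_segment(numeric(1000), 16000)
  expect_error(mel_spectrogram(wrong_sr, fc), "sample rate")
})

test_that("the DCT-II matrix is orthonormal over its span", {
  m <- nightcough:::dct_matrix(20L, 40L)
  expect_equal(m %*% t(m), diag(20), tolerance = 1e-12)
})

test_that("delta of a constant sequence is zero; of a ramp is the slope", {
  cst <- matrix(5, 3, 10)
  expect_equal(nightcough:::delta_rows(cst), matrix(0, 3, 10))
  ramp <- matrix(seq(0, 18, by = 2), 1)
  d <- nightcough:::delta_rows(ramp)
  expect_equal(d[1, 2:9], rep(2, 8))
  expect_equal(d[1, 1], 1)  # edge replication halves the first step
  expect_equal(d[1, 10], 1)
})

test_that("sex features have 41 rows and the documented frame count", {
  sr <- 22050
  n <- round(0.65 * sr)
  set.seed(2)
  a <- audio_segment(runif(n, -0.5, 0.5), sr)
  f <- extract_sex_features(a)
  expect_equal(nrow(f), 41L)
  expect_equal(ncol(f), 1L + (n - 4096L) %/% 256L)
  expect_equal(rownames(f)[c(1, 21, 41)], c("mfcc0", "dmfcc0", "dzcr"))
  expect_error(extract_sex_features(audio_segment(numeric(1000), sr)), "shorter")
})

test_that("the zero-crossing rate underlying dzcr matches a direct count", {
  sr <- 22050
  # 200 Hz square-ish wave: known crossing count per frame
  t <- (0:(8191)) / sr
  x <- sign(sin(2 * pi * 200 * t)) * 0.5
  x[x == 0] <- 0.5
  a <- audio_segment(x, sr)
  f <- extract_sex_features(a)
  # recompute frame-0 ZCR by hand and compare against the package's internal
  frame <- x[1:4096]
  zc <- sum(diff(sign(frame)) != 0) / 4095
  # dzcr row is the delta of zcr; reconstruct zcr is not exposed, so verify
  # indirectly: for a stationary signal the delta is ~0
  expect_lt(max(abs(f["dzcr", ])), 1e-3)
  expect_gt(zc, 0.01)
})
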