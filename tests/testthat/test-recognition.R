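small_fc <- feature_config()

test_that("cough events yield one window centered on the amplitude peak", {
  fc <- small_fc
  sr <- fc$sample_rate
  x <- numeric(5 * sr)
  peak_at <- 2 * sr + 1234L
  x[peak_at] <- 0.9
  x[peak_at + -300:300] <- x[peak_at + -300:300] + 0.2
  x <- pmin(1, x)
  a <- audio_segment(x, sr)
  ev <- label_track(2.0, 2.4, "cough")
  w <- extract_training_windows(ev, a, fc)
  expect_equal(dim(w$x), c(80L, 122L, 1L))
  expect_equal(w$y, 1L)
  # the same window recomputed directly from the peak index matches
  half <- fc$window_samples %/% 2L
  direct <- x[(peak_at - half):(peak_at - half + fc$window_samples - 1L)]
  expect_equal(w$x[, , 1],
               unclass(mel_spectrogram(audio_segment(direct, sr), fc)),
               ignore_attr = TRUE)
})

test_that("noncough events tile into floor(duration / 0.65) windows", {
  fc <- small_fc
  sr <- fc$sample_rate
  a <- audio_segment(runif(6 * sr, -0.3, 0.3), sr)
  ev <- label_track(c(0.5, 3.0), c(0.9, 5.0), c("noncough", "noncough"))
  w <- extract_training_windows(ev, a, fc)
  # 0.4 s event -> 1 centered window; 2.0 s event -> floor(2.0 / 0.65) = 3
  expect_equal(dim(w$x)[3], 4L)
  expect_equal(w$y, rep(0L, 4))
})

test_that("uncertain events and out-of-bounds events are rejected", {
  fc <- small_fc
  a <- audio_segment(numeric(2 * fc$sample_rate), fc$sample_rate)
  expect_error(
    extract_training_windows(label_track(0.1, 0.5, "uncertain"), a, fc),
    "uncertain")
  expect_error(
    extract_training_windows(label_track(1.5, 2.5, "cough"), a, fc),
    "outside")
})

test_that("window extraction zero-pads only beyond the recording bounds", {
  fc <- small_fc
  sr <- fc$sample_rate
  x <- runif(round(0.4 * sr), -0.5, 0.5)
  x[100] <- 0.95   # peak near the start
  a <- audio_segment(x, sr)
  ev <- label_track(1e-4, 0.4, "cough")
  w <- extract_training_windows(ev, a, fc)
  expect_equal(dim(w$x)[3], 1L)
  # energy must appear despite the event sitting at the recording edge
  expect_gt(max(w$x[, , 1]), -60)
})

test_that("folds are participant-disjunct for noncoughs and share all coughs", {
  set.seed(6)
  n_mels <- 4L; n_frames <- 5L
  n_parts <- 9L
  counts <- sample(3:10, n_parts, replace = TRUE)
  parts <- rep(sprintf("p%d", seq_len(n_parts)), counts)
  n_non <- length(parts)
  n_cough <- 7L
  windows <- list(
    x = array(rnorm(n_mels * n_frames * (n_non + n_cough)),
              c(n_mels, n_frames, n_non + n_cough)),
    y = c(rep(0L, n_non), rep(1L, n_cough)),
    participant = c(parts, rep("pc", n_cough)),
    night = rep("n1", n_non + n_cough)
  )
  folds <- make_disjunct_folds(windows, 5L, seed = 2L)
  expect_length(folds, 5L)
  non_parts <- lapply(folds, function(f) unique(f$participant[f$y == 0L]))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(non_parts[[i]], non_parts[[j]]), 0L)
  }
  expect_setequal(unlist(non_parts), unique(parts))
  for (f in folds) expect_equal(sum(f$y == 1L), n_cough)
  # total noncough windows preserved
  expect_equal(sum(vapply(folds, function(f) sum(f$y == 0L), 0L)), n_non)
  expect_error(make_disjunct_folds(list(x = windows$x, y = windows$y,
                                        participant = rep("a", n_non + n_cough)),
                                   5L), "distinct participants")
})

test_that("every balanced minibatch is exactly class-balanced", {
  y <- c(rep(0L, 57), rep(1L, 8))
  batches <- balanced_batches(y, 16L, n_batches = 40L, seed = 3L)
  expect_length(batches, 40L)
  for (b in batches) {
    expect_length(b, 16L)
    expect_equal(sum(y[b] == 1L), 8L)
    expect_equal(sum(y[b] == 0L), 8L)
  }
  # one pass consumes majority windows in disjoint chunks
  one_pass <- balanced_batches(y, 16L, seed = 3L)
  maj_used <- unlist(lapply(one_pass, function(b) b[y[b] == 0L]))
  expect_equal(anyDuplicated(maj_used), 0L)
  expect_error(balanced_batches(y, 15L), "even")
  expect_error(balanced_batches(rep(0L, 10), 4L), "both classes")
})

test_that("ensemble_predict averages member probabilities against the threshold", {
  arch <- tiny_arch()
  members <- lapply(1:5, function(i) init_cnn(arch, seed = i))
  model <- structure(list(members = members, threshold = 0.5, arch = arch),
                     class = "ensemble_model")
  set.seed(9)
  x <- array(rnorm(12 * 16 * 6), c(12L, 16L, 6L))
  pred <- ensemble_predict(model, x)
  manual <- rowMeans(vapply(members, function(m) predict_cnn(m, x), numeric(6)))
  expect_equal(pred$probability, manual, tolerance = 1e-12)
  expect_equal(pred$decision, manual >= 0.5)
  pred2 <- ensemble_predict(model, x, threshold = 0.9)
  expect_equal(pred2$decision, manual >= 0.9)
})

test_that("tune_threshold searches [0.5, 1) and needs both classes", {
  arch <- tiny_arch()
  members <- lapply(1:5, function(i) init_cnn(arch, seed = 10L + i))
  model <- structure(list(members = members, threshold = 0.5, arch = arch),
                     class = "ensemble_model")
  set.seed(10)
  windows <- list(x = array(rnorm(12 * 16 * 20), c(12L, 16L, 20L)),
                  y = rep(c(0L, 1L), 10))
  t <- tune_threshold(model, windows)
  expect_gte(t, 0.5)
  expect_lt(t, 1)
  expect_error(tune_threshold(model, list(x = windows$x, y = rep(1L, 20))),
               "both classes")
})

test_that("participant partition is disjoint with the requested fractions", {
  ids <- sprintf("p%02d", 1:40)
  sp <- partition_recognition_dataset(ids, seed = 4L)
  expect_length(sp$test, 8L)
  expect_length(sp$validation, 6L)
  expect_length(sp$train, 26L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
})
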