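test_that("postprocess implements the three published rules", {
  # rule 1: a run of 2..8 yields one cough at the covered-span center
  s <- make_series(c(0, 0.95, 0.96, 0, 0))
  det <- postprocess(s, 0.5)
  expect_equal(nrow(det), 1L)
  expect_equal(det$rule, "run")
  expect_equal(det$time, (0.065 + (2 * 0.065 + 0.65)) / 2)

  # rule 2: isolated single fires only if mean with the next window > 0.9
  s2 <- make_series(c(0, 0.95, 0.88, 0, 0))  # 0.88 below threshold 0.9
  expect_equal(nrow(postprocess(s2, 0.9)), 1L)   # mean(0.95, 0.88) = 0.915 > 0.9
  s3 <- make_series(c(0, 0.92, 0.2, 0, 0))
  expect_equal(nrow(postprocess(s3, 0.9)), 0L)   # mean(0.92, 0.2) <= 0.9
  expect_equal(postprocess(s2, 0.9)$rule, "single-lookahead")
  # isolated single at the very end has no lookahead window
  s4 <- make_series(c(0, 0, 0.99))
  expect_equal(nrow(postprocess(s4, 0.9)), 0L)

  # rule 3: a run of 9 yields exactly two coughs
  s5 <- make_series(c(0, rep(0.95, 9), 0))
  det5 <- postprocess(s5, 0.5)
  expect_equal(nrow(det5), 2L)
  expect_equal(det5$rule, rep("long-run-split", 2))
  expect_equal(det5$run_length, c(4L, 5L))

  # runs of exactly 8 still yield one
  s6 <- make_series(c(0, rep(0.95, 8), 0))
  expect_equal(nrow(postprocess(s6, 0.5)), 1L)

  expect_error(postprocess(s, 0.4), "0.5")
  expect_error(postprocess(s, 1.0), "0.5")
})

test_that("probabilities exactly at the threshold count as above", {
  s <- make_series(c(0, 0.7, 0.7, 0))
  expect_equal(nrow(postprocess(s, 0.7)), 1L)
})

test_that("derive_epochs applies the strict 2-second rule and drops singletons", {
  ep <- derive_epochs(c(1.0, 2.5, 3.9, 10.0, 30.0, 31.9))
  expect_equal(ep$epoch_count, 2L)
  expect_equal(ep$coughs_in_epochs, 5L)
  expect_equal(ep$epochs$n_coughs, c(3L, 2L))
  # a gap of exactly 2.0 s breaks the epoch (strict inequality)
  ep2 <- derive_epochs(c(0, 2.0))
  expect_equal(ep2$epoch_count, 0L)
  ep3 <- derive_epochs(c(0, 1.999))
  expect_equal(ep3$epoch_count, 1L)
  expect_equal(derive_epochs(numeric())$epoch_count, 0L)
  expect_error(derive_epochs(c(3, 1)), "sorted")
})

test_that("match_detections matches greedily within tolerance-dilated intervals", {
  ann <- label_track(c(10, 20, 30), c(10.4, 20.4, 30.4), rep("cough", 3))
  m <- match_detections(c(10.2, 20.7, 25.0), ann, tolerance = 0.5)
  expect_equal(m$counts, list(tp = 2L, fp = 1L, fn = 1L))
  # outside the dilated interval
  m2 <- match_detections(c(21.0), ann, tolerance = 0.5)
  expect_equal(m2$counts$tp, 0L)
  # one-to-one: two predictions cannot claim the same annotation
  m3 <- match_detections(c(10.1, 10.3), ann, tolerance = 0.5)
  expect_equal(m3$counts, list(tp = 1L, fp = 1L, fn = 2L))
  expect_error(match_detections(1, ann, tolerance = -1), "nonnegative")
})

test_that("epoch-level matching requires matched coughs inside predicted epochs", {
  # annotated epoch of 3 coughs at 10, 11, 12; isolated cough at 30
  ann <- label_track(c(10, 11, 12, 30), c(10.3, 11.3, 12.3, 30.3), rep("cough", 4))
  # predictions recover the epoch
  m <- match_detections(c(10.1, 11.1, 12.1, 30.1), ann)
  expect_equal(m$epochs$tp, 1L)
  expect_equal(m$epochs$fn, 0L)
  expect_equal(m$epochs$annotated, 1L)
  # a single matched cough not in any predicted epoch does not detect it
  m2 <- match_detections(c(11.1), ann)
  expect_equal(m2$epochs$tp, 0L)
  expect_equal(m2$epochs$fn, 1L)
})

test_that("slide_and_score windows stride correctly and skip quiet windows", {
  fit <- list(model = structure(
    list(members = lapply(1:5, function(i) init_cnn(cnn_architecture(desk = TRUE),
                                                    seed = i)),
         threshold = 0.5),
    class = "ensemble_model"))
  fc <- feature_config()
  sr <- fc$sample_rate
  x <- numeric(3 * sr)
  x[(sr + 1):(sr + 2000)] <- runif(2000, -0.5, 0.5)  # one loud burst at 1 s
  a <- audio_segment(x, sr)
  s <- slide_and_score(a, fit$model, fc)
  expect_s3_class(s, "probability_series")
  expect_equal(attr(s, "stride"), round(0.065 * sr) / sr)
  expect_equal(diff(s$time)[1], round(0.065 * sr) / sr)
  # quiet windows flagged silent with probability zero
  expect_true(all(s$probability[s$silent] == 0))
  # windows overlapping the burst are not silent (peak measure); the block-
  # quantized peak can also clear the window immediately before the burst
  stride <- attr(s, "stride")
  overlap <- s$time + 0.65 > 1 & s$time < 1 + 2000 / sr
  loose <- s$time + 0.65 + stride > 1 & s$time < 1 + 2000 / sr
  expect_true(all(!s$silent[overlap]))
  expect_true(all(s$silent[!loose]))
  # rms measure: the short burst no longer clears the window-RMS threshold
  s_rms <- slide_and_score(a, fit$model, fc, measure = "rms")
  expect_gt(sum(s_rms$silent), sum(s$silent))
  expect_error(slide_and_score(audio_segment(numeric(1000), sr), fit$model, fc),
               "shorter")
})

test_that("tune_segmentation_threshold returns the midpoint of the optimal plateau", {
  # construct series whose count error is zero exactly for t in [0.60, 0.80]:
  # truth 1 cough; probabilities 0.59 (shoulder), core of 3 at 0.81,
  # plus a spurious pair at 0.59. For t <= 0.59 both runs fire (count 2);
  # 0.60..0.81 one run fires; above 0.81 nothing fires.
  p <- c(0, 0.59, 0.81, 0.81, 0.81, 0, 0, 0.59, 0.59, 0)
  s <- make_series(p)
  th <- tune_segmentation_threshold(list(s), 1L)
  expect_gte(th, 0.60)
  expect_lte(th, 0.81)
  expect_equal(th, 0.70)  # grid plateau 0.60..0.81 -> midpoint
  expect_error(tune_segmentation_threshold(list(s), c(1L, 2L)))
})

test_that("segment_recording composes scoring, postprocessing and epochs", {
  fit <- noiseless_segmentation_fit()
  night <- synth_night(night_config(duration = 120, seed = 77L,
                                    background_level_db = -Inf))
  seg <- segment_recording(night$audio, fit$model, fit$feature)
  expect_named(seg, c("detections", "epochs", "cough_count", "epoch_count",
                      "coughs_in_epochs"))
  expect_equal(seg$cough_count, nrow(seg$detections))
  manual_ep <- derive_epochs(seg$detections$time)
  expect_equal(seg$epoch_count, manual_ep$epoch_count)
})
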