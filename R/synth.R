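# Synthetic night-audio generator.
#
# Emulates the statistical structure of overnight bedroom recordings: long,
# mostly quiet pink-noise background punctuated by short acoustic events, a
# minority of which are coughs; coughs cluster into epochs (inter-cough gaps
# well under 2 s) separated from all other events by comfortably more than
# 2 s, so ground-truth epoch structure is unambiguous under the 2-second rule.

MALE_F0_RANGE <- c(85, 180)
FEMALE_F0_RANGE <- c(165, 255)
NONCOUGH_KINDS <- c("snore", "tone", "chirp", "thump", "babble")

#' Specification of one synthetic cough
#'
#' A synthetic cough is an explosive broadband burst (5 ms attack, ~150 ms
#' decay) followed by a voiced harmonic tail at fundamental frequency `f0`.
#' The sex-typical fundamental-frequency ranges are 85-180 Hz (male) and
#' 165-255 Hz (female); by default f0 is drawn uniformly from the sex's range
#' with the 165-180 Hz overlap region excluded, so synthetic ground truth is
#' unambiguous. Set `allow_overlap = TRUE` to re-enable the shared band.
#'
#' @param sex `"female"` or `"male"`.
#' @param f0 Fundamental frequency of the voiced tail in Hz; if `NULL`, drawn
#'   from the sex's range (caller must seed the RNG for reproducibility).
#' @param burst_duration Total event duration in seconds, in \[0.2, 0.65\].
#' @param peak_level_db Peak level in dBFS (must exceed -26 so the event
#'   passes the silence filter).
#' @param allow_overlap Allow f0 in the 165-180 Hz male/female overlap.
#' @return A `cough_spec` list.
#' @export
cough_spec <- function(sex, f0 = NULL, burst_duration = 0.45, peak_level_db = -12,
                       allow_overlap = FALSE) {
  sex <- match.arg(sex, c("female", "male"))
  rng <- sex_f0_range(sex, allow_overlap)
  if (is.null(f0)) f0 <- runif(1, rng[1], rng[2])
  if (f0 < rng[1] || f0 > rng[2]) {
    stopf("f0 = %.1f Hz outside the %s range [%.0f, %.0f] Hz", f0, sex, rng[1], rng[2])
  }
  if (burst_duration < 0.2 || burst_duration > 0.65) {
    stopf("burst_duration must lie in [0.2, 0.65] s, got %.3f", burst_duration)
  }
  if (peak_level_db <= -26) {
    stopf("peak_level_db must exceed -26 dBFS (silence threshold), got %g", peak_level_db)
  }
  structure(list(sex = sex, f0 = f0, burst_duration = burst_duration,
                 peak_level_db = peak_level_db), class = "cough_spec")
}

sex_f0_range <- function(sex, allow_overlap = FALSE) {
  if (sex == "male") {
    if (allow_overlap) MALE_F0_RANGE else c(MALE_F0_RANGE[1], FEMALE_F0_RANGE[1])
  } else {
    if (allow_overlap) FEMALE_F0_RANGE else c(MALE_F0_RANGE[2], FEMALE_F0_RANGE[2])
  }
}

#' Synthesize one cough
#'
#' Deterministic given `seed`: a white-noise burst shaped by a 5 ms attack /
#' 150 ms exponential decay envelope, plus a voiced tail of 5 harmonics at
#' `spec$f0` (amplitudes 1/h) occupying the final 70% of the event. The peak
#' amplitude is normalized to `spec$peak_level_db`.
#'
#' @param spec A [cough_spec()].
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param seed Integer seed; identical seeds give bit-identical waveforms.
#' @return An [audio_segment()] of length `spec$burst_duration`.
#' @export
synth_cough <- function(spec, sample_rate = 22050, seed = NULL) {
  stopifnot(inherits(spec, "cough_spec"))
  if (sample_rate < 8000) stopf("sample_rate must be >= 8000 Hz")
  with_seed(seed, {
    n <- round(spec$burst_duration * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    # explosive phase: noise with 5 ms linear attack, exp decay (~5% at 150 ms)
    attack <- pmin(1, t / 0.005)
    env_burst <- attack * exp(-t / 0.05)
    burst <- rnorm(n) * env_burst
    # voiced tail: harmonic stack at f0, raised-cosine on/off ramps
    tail_start <- 0.3 * spec$burst_duration
    tail_len <- spec$burst_duration - tail_start
    u <- (t - tail_start) / tail_len
    env_tail <- ifelse(u > 0 & u < 1, sin(pi * pmin(pmax(u, 0), 1))^2, 0)
    phases <- runif(5, 0, 2 * pi)
    tail <- numeric(n)
    for (h in 1:5) tail <- tail + (1 / h) * sin(2 * pi * h * spec$f0 * t + phases[h])
    x <- burst / max(abs(burst)) + 0.6 * env_tail * tail / max(abs(tail))
    x <- x / max(abs(x)) * db_to_amp(spec$peak_level_db)
    audio_segment(x, sample_rate)
  })
}

#' Synthesize one noncough event
#'
#' Spectrally distinct archetypes of common bedroom sounds: `snore`
#' (low-passed noise with slow amplitude modulation), `tone` (steady
#' sinusoid), `chirp` (linear frequency sweep), `thump` (broadband burst with
#' fast decay and no voiced tail), `babble` (band-limited noise with syllabic
#' amplitude modulation).
#'
#' @param kind One of `snore`, `tone`, `chirp`, `thump`, `babble`.
#' @param duration Event duration in seconds.
#' @param peak_level_db Peak level in dBFS (> -26).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An [audio_segment()].
#' @export
synth_noncough <- function(kind, duration = 0.8, peak_level_db = -12,
                           sample_rate = 22050, seed = NULL) {
  kind <- match.arg(kind, NONCOUGH_KINDS)
  if (peak_level_db <= -26) stopf("peak_level_db must exceed -26 dBFS")
  with_seed(seed, {
    n <- round(duration * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    ramp <- pmin(1, t / 0.02) * pmin(1, (duration - t) / 0.02)
    x <- switch(kind,
      snore = {
        lp <- stats::filter(rnorm(n), rep(1 / 32, 32), sides = 1)
        lp[is.na(lp)] <- 0
        as.numeric(lp) * (0.55 + 0.45 * sin(2 * pi * runif(1, 3, 6) * t))
      },
      tone = sin(2 * pi * runif(1, 500, 4000) * t),
      chirp = {
        f0 <- runif(1, 200, 600); f1 <- runif(1, 2000, 5000)
        sin(2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2))
      },
      thump = {
        env <- exp(-t / 0.02)
        lp <- stats::filter(rnorm(n), rep(1 / 8, 8), sides = 1)
        lp[is.na(lp)] <- 0
        as.numeric(lp) * env
      },
      babble = {
        bp <- stats::filter(rnorm(n), rep(1 / 6, 6), sides = 1)
        bp[is.na(bp)] <- 0
        as.numeric(bp) * (0.4 + 0.6 * abs(sin(2 * pi * runif(1, 2, 4) * t)))
      }
    )
    x <- x * ramp
    x <- x / max(abs(x)) * db_to_amp(peak_level_db)
    audio_segment(x, sample_rate)
  })
}

#' Configuration of a synthetic night
#'
#' @param duration Night duration in seconds (> 0).
#' @param cough_epoch_rate Expected cough epochs per hour.
#' @param coughs_per_epoch_range Integer range of coughs per epoch.
#' @param intra_epoch_gap_range Range (seconds) of within-epoch end-to-start
#'   gaps; the upper bound must stay below 2 s so planted epochs are real
#'   epochs under the 2-second rule.
#' @param isolated_cough_rate Expected singleton coughs per hour.
#' @param noncough_event_rate Expected noncough events per hour.
#' @param noncough_kinds Subset of `snore`, `tone`, `chirp`, `thump`,
#'   `babble`.
#' @param sex Sex of the synthetic cougher (`"female"` or `"male"`).
#' @param background_level_db RMS level of the pink-noise background in dBFS;
#'   must be below -26 so pure background is classified as silence.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed driving all draws.
#' @return A `night_config` list.
#' @export
night_config <- function(duration = 600, cough_epoch_rate = 6,
                         coughs_per_epoch_range = c(2L, 5L),
                         intra_epoch_gap_range = c(0.3, 1.0),
                         isolated_cough_rate = 6, noncough_event_rate = 30,
                         noncough_kinds = NONCOUGH_KINDS, sex = "female",
                         background_level_db = -50, sample_rate = 22050,
                         seed = 1L) {
  sex <- match.arg(sex, c("female", "male"))
  if (duration <= 0) stopf("duration must be positive")
  if (cough_epoch_rate < 0 || isolated_cough_rate < 0 || noncough_event_rate < 0) {
    stopf("event rates must be nonnegative")
  }
  if (intra_epoch_gap_range[2] >= 2.0) {
    stopf("intra_epoch_gap_range upper bound must be < 2 s (got %.2f)", intra_epoch_gap_range[2])
  }
  if (background_level_db >= -26) {
    stopf("background_level_db must be below -26 dBFS (got %g)", background_level_db)
  }
  stopifnot(all(noncough_kinds %in% NONCOUGH_KINDS),
            coughs_per_epoch_range[1] >= 2L)
  structure(list(
    duration = duration, cough_epoch_rate = cough_epoch_rate,
    coughs_per_epoch_range = as.integer(coughs_per_epoch_range),
    intra_epoch_gap_range = intra_epoch_gap_range,
    isolated_cough_rate = isolated_cough_rate,
    noncough_event_rate = noncough_event_rate,
    noncough_kinds = noncough_kinds, sex = sex,
    background_level_db = background_level_db,
    sample_rate = sample_rate, seed = as.integer(seed)
  ), class = "night_config")
}

# pink-ish (1/f) noise via Kellet's cascade of one-pole filters, unit RMS
pink_noise <- function(n) {
  w <- rnorm(n)
  b1 <- as.numeric(stats::filter(0.0990460 * w, 0.99765, method = "recursive"))
  b2 <- as.numeric(stats::filter(0.2965164 * w, 0.96300, method = "recursive"))
  b3 <- as.numeric(stats::filter(1.0526913 * w, 0.57000, method = "recursive"))
  p <- b1 + b2 + b3 + 0.1848 * w
  p / sqrt(mean(p^2))
}

#' Generate a synthetic night with ground-truth annotations
#'
#' Plants Poisson-distributed counts of cough epochs, isolated coughs, and
#' noncough events into a pink-noise background at non-overlapping positions
#' separated by at least 3 s, and returns both the audio and a label track of
#' true event boundaries (`cough` or `noncough:<kind>`).
#'
#' @param config A [night_config()].
#' @return A list with elements `audio` ([audio_segment()]), `labels`
#'   ([label_track()]), and `events` (data frame with per-event metadata:
#'   onset, offset, label, f0, epoch id or NA).
#' @export
synth_night <- function(config) {
  stopifnot(inherits(config, "night_config"))
  with_seed(config$seed, {
    sr <- config$sample_rate
    hours <- config$duration / 3600
    n_epochs <- stats::rpois(1, config$cough_epoch_rate * hours)
    n_iso <- stats::rpois(1, config$isolated_cough_rate * hours)
    n_non <- stats::rpois(1, config$noncough_event_rate * hours)

    # Build event "blocks" first; a block is an epoch (coughs + intra gaps),
    # a single cough, or a single noncough event.
    blocks <- list()
    for (e in seq_len(n_epochs)) {
      k <- sample(seq(config$coughs_per_epoch_range[1], config$coughs_per_epoch_range[2]), 1)
      durs <- runif(k, 0.3, 0.55)
      gaps <- runif(k - 1, config$intra_epoch_gap_range[1], config$intra_epoch_gap_range[2])
      blocks[[length(blocks) + 1L]] <- list(type = "epoch", durs = durs, gaps = gaps,
                                            len = sum(durs) + sum(gaps))
    }
    for (i in seq_len(n_iso)) {
      d <- runif(1, 0.3, 0.55)
      blocks[[length(blocks) + 1L]] <- list(type = "cough", durs = d, gaps = numeric(), len = d)
    }
    for (i in seq_len(n_non)) {
      kind <- sample(config$noncough_kinds, 1)
      d <- runif(1, 0.4, 1.6)
      blocks[[length(blocks) + 1L]] <- list(type = "noncough", kind = kind, durs = d,
                                            gaps = numeric(), len = d)
    }
    min_gap <- 3.0
    nb <- length(blocks)
    total_len <- sum(vapply(blocks, `[[`, numeric(1), "len"))
    slack <- config$duration - total_len - (nb + 1L) * min_gap
    if (nb > 0 && slack <= 0) {
      stopf("event density too high: %.1f s of events + gaps exceed %.1f s night",
            total_len + (nb + 1L) * min_gap, config$duration)
    }

    audio <- pink_noise(round(config$duration * sr)) * db_to_amp(config$background_level_db)
    ev_start <- numeric(); ev_end <- numeric(); ev_label <- character()
    ev_f0 <- numeric(); ev_epoch <- integer()

    if (nb > 0) {
      # random order, random non-overlapping placement: split the slack
      # uniformly over the nb+1 inter-block gaps
      ord <- sample(nb)
      u <- runif(nb + 1L)
      extra <- slack * u / sum(u)
      cursor <- min_gap + extra[1]
      epoch_id <- 0L
      for (bi in seq_len(nb)) {
        b <- blocks[[ord[bi]]]
        t0 <- cursor
        if (b$type == "noncough") {
          seg <- synth_noncough(b$kind, duration = b$durs, sample_rate = sr,
                                peak_level_db = runif(1, -18, -8))
          i0 <- round(t0 * sr) + 1L
          idx <- i0:(i0 + length(seg$samples) - 1L)
          audio[idx] <- audio[idx] + seg$samples
          ev_start <- c(ev_start, t0); ev_end <- c(ev_end, t0 + b$durs)
          ev_label <- c(ev_label, paste0("noncough:", b$kind))
          ev_f0 <- c(ev_f0, NA_real_); ev_epoch <- c(ev_epoch, NA_integer_)
          cursor <- t0 + b$durs
        } else {
          if (b$type == "epoch") epoch_id <- epoch_id + 1L
          tt <- t0
          for (ci in seq_along(b$durs)) {
            spec <- cough_spec(config$sex, burst_duration = b$durs[ci],
                               peak_level_db = runif(1, -16, -6))
            seg <- synth_cough(spec, sample_rate = sr)
            i0 <- round(tt * sr) + 1L
            idx <- i0:(i0 + length(seg$samples) - 1L)
            audio[idx] <- audio[idx] + seg$samples
            ev_start <- c(ev_start, tt); ev_end <- c(ev_end, tt + b$durs[ci])
            ev_label <- c(ev_label, "cough")
            ev_f0 <- c(ev_f0, spec$f0)
            ev_epoch <- c(ev_epoch, if (b$type == "epoch") epoch_id else NA_integer_)
            tt <- tt + b$durs[ci] + if (ci < length(b$durs)) b$gaps[ci] else 0
          }
          cursor <- tt
        }
        cursor <- cursor + min_gap + extra[bi + 1L]
      }
    }
    audio <- pmin(1, pmax(-1, audio))
    o <- order(ev_start)
    events <- data.frame(
      start = ev_start[o], end = ev_end[o], label = ev_label[o],
      f0 = ev_f0[o], epoch = ev_epoch[o], stringsAsFactors = FALSE
    )
    labels <- if (nrow(events)) label_track(events$start, events$end, events$label) else label_track()
    list(audio = audio_segment(audio, sr), labels = labels, events = events)
  })
}
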