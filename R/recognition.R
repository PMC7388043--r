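# Imbalance-aware ensemble cough/noncough window recognition: training-window
# extraction, participant-disjunct folds, balanced minibatches, threshold
# tuning, and the averaged-probability ensemble decision rule.

#' Extract labeled 650 ms training windows from annotated events
#'
#' Each noncough event yields `floor(duration / 0.65)` nonoverlapping windows
#' (at least one, centered on the event, for shorter events). Each cough
#' event yields one cough-labeled window per entry of `cough_offsets`: the
#' window spans 325 ms either side of the event's absolute-amplitude maximum,
#' shifted by the offset (seconds). Optionally, `shoulder_offsets` adds
#' noncough-labeled windows at larger shifts from the same peak. Shoulder
#' windows teach the classifier that a window which has slid past the burst
#' is no longer "a cough", which keeps the sliding-window response to one
#' cough narrow — the property the run-length counting rules rely on.
#' Windows carry the recording's content over their span — including
#' background around short events, as in real annotated recordings — and are
#' zero-padded only where they extend beyond the audio itself (so an event
#' that is the whole recording comes out symmetrically zero-padded). Events
#' labeled `uncertain` must already be removed.
#'
#' @param events A [label_track()] with labels `cough` or `noncough`
#'   (optionally `noncough:<kind>`).
#' @param audio The [audio_segment()] the events refer to.
#' @param config A [feature_config()].
#' @param participant_id,night_id Identifiers attached to every window.
#' @param cough_offsets Center offsets (s) of cough-labeled windows relative
#'   to each cough event's peak (default `0`: one peak-centered window).
#' @param shoulder_offsets Center offsets (s) of additional noncough-labeled
#'   windows around each cough peak (default none).
#' @return A list with `x` (array `n_mels x n_frames x n_windows` of log-Mel
#'   spectrograms), `y` (1 = cough, 0 = noncough), `participant`, `night`.
#' @export
extract_training_windows <- function(events, audio, config = feature_config(),
                                     participant_id = "p1", night_id = "n1",
                                     cough_offsets = 0,
                                     shoulder_offsets = numeric(0)) {
  stopifnot(inherits(events, "label_track"), inherits(audio, "audio_segment"))
  if (any(events$label == "uncertain")) {
    stopf("uncertain events must be discarded before window extraction")
  }
  sr <- audio$sample_rate
  dur <- audio_duration(audio)
  if (any(events$start < 0 | events$end > dur + 1e-9)) {
    stopf("event outside audio bounds [0, %.3f]", dur)
  }
  wlen <- config$window_samples
  half <- wlen %/% 2L
  n_audio <- length(audio$samples)
  # audio content over [s0, s0 + wlen), zero-padded beyond the recording
  take_window <- function(s0) {
    src <- s0:(s0 + wlen - 1L)
    ok <- src >= 1L & src <= n_audio
    w <- numeric(wlen)
    w[ok] <- audio$samples[src[ok]]
    w
  }
  xs <- list()
  ys <- integer()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    is_cough <- ev$label == "cough"
    i0 <- floor(ev$start * sr) + 1L
    i1 <- min(n_audio, ceiling(ev$end * sr))
    ev_len <- i1 - i0 + 1L
    if (is_cough) {
      m <- i0 + which.max(abs(audio$samples[i0:i1])) - 1L  # peak sample
      for (off in cough_offsets) {
        xs[[length(xs) + 1L]] <- take_window(m + round(off * sr) - half)
        ys <- c(ys, 1L)
      }
      for (off in shoulder_offsets) {
        xs[[length(xs) + 1L]] <- take_window(m + round(off * sr) - half)
        ys <- c(ys, 0L)
      }
    } else if (ev_len < wlen) {
      mid <- (i0 + i1) %/% 2L
      xs[[length(xs) + 1L]] <- take_window(mid - half)
      ys <- c(ys, 0L)
    } else {
      k <- ev_len %/% wlen
      for (j in seq_len(k)) {
        xs[[length(xs) + 1L]] <- take_window(i0 + (j - 1L) * wlen)
        ys <- c(ys, 0L)
      }
    }
  }
  n <- length(xs)
  x <- array(0, c(config$n_mels, config$n_frames, n))
  for (i in seq_len(n)) {
    x[, , i] <- mel_spectrogram(audio_segment(xs[[i]], sr), config)
  }
  list(x = x, y = ys,
       participant = rep(participant_id, n), night = rep(night_id, n))
}

#' Combine window sets from several recordings
#'
#' @param ... Window sets as returned by [extract_training_windows()].
#' @return One combined window set.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.null(parts[[1]]$x)) parts <- parts[[1]]
  x <- array(0, c(dim(parts[[1]]$x)[1:2], sum(vapply(parts, function(p) dim(p$x)[3], 0))))
  at <- 0L
  for (p in parts) {
    k <- dim(p$x)[3]
    if (k) x[, , at + seq_len(k)] <- p$x
    at <- at + k
  }
  list(x = x, y = unlist(lapply(parts, `[[`, "y")),
       participant = unlist(lapply(parts, `[[`, "participant")),
       night = unlist(lapply(parts, `[[`, "night")))
}

#' Partition noncough windows into participant-disjunct folds
#'
#' The noncough windows are split by participant into `n_folds` groups of
#' near-equal window counts (greedy assignment: participants in decreasing
#' window count, each to the currently smallest fold). Every fold is paired
#' with the full cough set, reducing the class imbalance seen by each member.
#'
#' @param windows A window set ([extract_training_windows()] /
#'   [bind_windows()]).
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for tie-breaking among equal-count participants.
#' @return List of `n_folds` folds, each a window set (`x`, `y`, ...).
#' @export
make_disjunct_folds <- function(windows, n_folds = 5L, seed = 1L) {
  non_idx <- which(windows$y == 0L)
  cough_idx <- which(windows$y == 1L)
  parts <- unique(windows$participant[non_idx])
  if (length(parts) < n_folds) {
    stopf("need >= %d distinct participants with noncough windows, have %d",
          n_folds, length(parts))
  }
  counts <- table(windows$participant[non_idx])[parts]
  ord <- with_seed(seed, {
    jitter_order <- sample(length(parts))           # random tie-break
    parts[order(-as.integer(counts), jitter_order)]
  })
  fold_of <- integer(length(ord)); names(fold_of) <- ord
  sizes <- integer(n_folds)
  for (p in ord) {
    f <- which.min(sizes)
    fold_of[p] <- f
    sizes[f] <- sizes[f] + counts[[p]]
  }
  lapply(seq_len(n_folds), function(f) {
    keep <- c(non_idx[fold_of[windows$participant[non_idx]] == f], cough_idx)
    list(x = windows$x[, , keep, drop = FALSE], y = windows$y[keep],
         participant = windows$participant[keep], night = windows$night[keep])
  })
}

#' Balanced minibatch index sequence
#'
#' Every batch contains exactly `batch_size / 2` windows of each class. The
#' majority class is shuffled and consumed in chunks (one pass = one epoch);
#' the minority class is sampled with replacement for every batch. When
#' `n_batches` exceeds one pass, the majority class is reshuffled per pass.
#'
#' @param y 0/1 label vector of the fold.
#' @param batch_size Even batch size.
#' @param n_batches Number of batches to emit; default one pass over the
#'   majority class.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return List of integer index vectors into `y`.
#' @export
balanced_batches <- function(y, batch_size, n_batches = NULL, seed = NULL) {
  if (batch_size %% 2L != 0L) stopf("batch_size must be even, got %d", batch_size)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  if (!length(i1) || !length(i0)) stopf("both classes must be present in the fold")
  maj <- if (length(i0) >= length(i1)) i0 else i1
  mino <- if (length(i0) >= length(i1)) i1 else i0
  half <- batch_size %/% 2L
  per_pass <- max(1L, length(maj) %/% half)
  if (is.null(n_batches)) n_batches <- per_pass
  with_seed(seed, {
    out <- vector("list", n_batches)
    b <- 0L
    while (b < n_batches) {
      perm <- sample(maj)
      for (k in seq_len(per_pass)) {
        if (b >= n_batches) break
        b <- b + 1L
        maj_sel <- if (length(maj) >= half) {
          perm[((k - 1L) * half + 1L):(k * half)]
        } else {
          sample(maj, half, replace = TRUE)
        }
        out[[b]] <- c(maj_sel, sample(mino, half, replace = TRUE))
      }
    }
    out
  })
}

#' Train the 5-member ensemble
#'
#' Trains one CNN per participant-disjunct fold with balanced minibatches.
#'
#' @param folds Output of [make_disjunct_folds()].
#' @param config A [training_config()]; member `i` trains with seed
#'   `config$seed + i`.
#' @param arch A [cnn_architecture()].
#' @return An `ensemble_model`: 5 `cnn_model`s and a threshold (initially
#'   0.5; tune with [tune_threshold()]).
#' @export
train_ensemble <- function(folds, config = training_config(), arch = cnn_architecture()) {
  members <- lapply(seq_along(folds), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    train_member(folds[[i]], cfg, arch)
  })
  structure(list(members = members, threshold = 0.5, arch = arch),
            class = "ensemble_model")
}

# mean member probability for an array of spectrogram windows
ensemble_scores <- function(model, x) {
  probs <- vapply(model$members, function(m) predict_cnn(m, x),
                  numeric(if (is.matrix(x)) 1L else dim(x)[3]))
  if (is.null(dim(probs))) mean(probs) else rowMeans(probs)
}

#' Ensemble decision for spectrogram windows
#'
#' The ensemble probability is the arithmetic mean of the member
#' probabilities; the decision is cough iff the mean is at or above the
#' threshold `t` (a score exactly at `t` counts as cough).
#'
#' @param model An `ensemble_model`.
#' @param x A `mel_spectrogram` matrix or array `(n_mels, n_frames, n)`.
#' @param threshold Decision threshold; defaults to the model's.
#' @return A list with `probability` and logical `decision`.
#' @export
ensemble_predict <- function(model, x, threshold = model$threshold) {
  stopifnot(inherits(model, "ensemble_model"), length(model$members) == 5L)
  p <- ensemble_scores(model, x)
  list(probability = p, decision = p >= threshold)
}

#' Tune the ensemble decision threshold by grid search
#'
#' Evaluates the Matthews correlation coefficient of the averaged-probability
#' decision on a validation window set over the grid \[0.5, 1) and returns
#' the maximizing threshold (ties broken toward the smallest value).
#' Thresholds whose MCC is undefined (degenerate confusion table) are never
#' selected unless every grid value is undefined.
#'
#' @param model An `ensemble_model` (or a list of member `cnn_model`s).
#' @param windows Validation window set with both classes present.
#' @param grid_step Grid spacing (default 0.01).
#' @return The selected threshold in \[0.5, 1).
#' @export
tune_threshold <- function(model, windows, grid_step = 0.01) {
  if (!inherits(model, "ensemble_model")) {
    model <- structure(list(members = model, threshold = 0.5), class = "ensemble_model")
  }
  y <- windows$y
  if (length(unique(y)) < 2L) stopf("validation set must contain both classes (MCC undefined)")
  p <- ensemble_scores(model, windows$x)
  grid <- seq(0.5, 1 - grid_step, by = grid_step)
  mccs <- vapply(grid, function(t) {
    pred <- as.integer(p >= t)
    cm <- confusion_counts(pred, y)
    confusion_metrics(cm)$mcc
  }, numeric(1))
  if (all(is.na(mccs))) return(grid[1])
  grid[which.max(mccs)]   # which.max: first maximum -> smallest t on ties
}

#' Participant-level train/validation/test split
#'
#' Splits participants roughly 65:15:20: 20% of all participants are drawn
#' for the test set, then 15% (of the original count) from the remainder for
#' validation; the rest train. For final-model training, train and
#' validation are conventionally merged after hyperparameter selection.
#'
#' @param participants Character vector of participant ids.
#' @param seed Integer seed.
#' @param test_frac,val_frac Split fractions (defaults 0.20 and 0.15).
#' @return List with `train`, `validation`, `test` id vectors.
#' @export
partition_recognition_dataset <- function(participants, seed = 1L,
                                          test_frac = 0.20, val_frac = 0.15) {
  participants <- unique(participants)
  n <- length(participants)
  with_seed(seed, {
    test <- sample(participants, max(1L, round(test_frac * n)))
    rest <- setdiff(participants, test)
    val <- sample(rest, max(1L, round(val_frac * n)))
    list(train = setdiff(rest, val), validation = val, test = test)
  })
}
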