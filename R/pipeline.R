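# End-to-end orchestration: simulate -> train -> tune threshold -> segment ->
# epochs -> sex-assign -> evaluate, with one global seed fanned out to
# per-stage seeds by fixed offsets so stages can be re-run in isolation.

#' Run configuration for the end-to-end pipeline
#'
#' @param seed Global seed; stage seeds are derived by fixed offsets.
#' @param n_train_participants,n_test_participants Synthetic corpus sizes for
#'   recognition training / held-out evaluation.
#' @param events_per_participant Cough and noncough event counts per
#'   synthetic participant (named list with `cough`, `noncough`).
#' @param n_nights,night_duration Segmentation evaluation corpus.
#' @param n_val_nights Validation nights for segmentation-threshold
#'   calibration.
#' @param sex_coughs_per_class Coughs per sex for the GMM corpus.
#' @param arch A [cnn_architecture()].
#' @param training A [training_config()].
#' @param feature A [feature_config()].
#' @param gmm_k,gmm_n_init,gmm_iterations GMM hyperparameters.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_train_participants = 30L, n_test_participants = 10L,
                       events_per_participant = list(cough = 5L, noncough = 50L),
                       n_nights = 20L, night_duration = 600, n_val_nights = 4L,
                       sex_coughs_per_class = 120L,
                       arch = cnn_architecture(desk = TRUE),
                       training = training_config(),
                       feature = feature_config(),
                       gmm_k = 30L, gmm_n_init = 3L, gmm_iterations = 200L) {
  structure(as.list(environment()), class = "run_config")
}

#' Build a labeled synthetic window corpus for recognition
#'
#' Simulates annotated cough and noncough events for `n_participants`
#' synthetic participants and extracts labeled training windows from each.
#' Each event is embedded in a pink-noise background recording (default
#' -50 dBFS, the night generator's level) with margins around the event, so
#' training windows carry the same background statistics as sliding windows
#' over a night.
#'
#' Cough windows are extracted with a small uniform center jitter
#' (`cough_jitter`) so the positive class is seen at varying alignments, and
#' each cough also contributes two noncough-labeled shoulder windows (center
#' `shoulder_offset` seconds either side of the peak); both choices mirror
#' the sliding-window distribution the deployed classifier scores.
#'
#' @param n_participants Number of synthetic participants.
#' @param coughs,noncoughs Events per participant.
#' @param sexes Sex assignment per participant (recycled).
#' @param config A [feature_config()].
#' @param background_level_db Background pink-noise level in dBFS.
#' @param cough_jitter Half-width (s) of the uniform center jitter of cough
#'   windows.
#' @param shoulder_offset Center offset (s) of the two noncough-labeled
#'   shoulder windows per cough; `NULL` disables them.
#' @param seed Integer seed.
#' @return A window set ([bind_windows()] format).
#' @export
synth_window_corpus <- function(n_participants, coughs = 5L, noncoughs = 50L,
                                sexes = c("female", "male"),
                                config = feature_config(),
                                background_level_db = -50,
                                cough_jitter = 0.10, shoulder_offset = 0.33,
                                seed = 1L) {
  sexes <- rep(sexes, length.out = n_participants)
  with_seed(seed, {
    parts <- lapply(seq_len(n_participants), function(i) {
      sr <- config$sample_rate
      xs <- list(); ys <- integer()
      for (j in seq_len(coughs)) {
        spec <- cough_spec(sexes[i], burst_duration = runif(1, 0.3, 0.55),
                           peak_level_db = runif(1, -16, -6))
        xs[[length(xs) + 1L]] <- synth_cough(spec, sr)$samples
        ys <- c(ys, 1L)
      }
      for (j in seq_len(noncoughs)) {
        kind <- sample(NONCOUGH_KINDS, 1)
        seg <- synth_noncough(kind, duration = runif(1, 0.4, 1.6),
                              peak_level_db = runif(1, -18, -8), sample_rate = sr)
        xs[[length(xs) + 1L]] <- seg$samples
        ys <- c(ys, 0L)
      }
      # embed each event in a short pink-noise recording with margins large
      # enough for the shoulder windows, so every extracted window sees
      # realistic background around the event
      margin <- config$window_duration +
        if (is.null(shoulder_offset)) 0 else shoulder_offset
      sets <- lapply(seq_along(xs), function(e) {
        n_ev <- length(xs[[e]])
        n_tot <- n_ev + 2L * round(margin * sr)
        bg <- pink_noise(n_tot) * db_to_amp(background_level_db)
        at <- round(margin * sr)
        bg[at + seq_len(n_ev)] <- bg[at + seq_len(n_ev)] + xs[[e]]
        a <- audio_segment(pmin(1, pmax(-1, bg)), sr)
        lab <- if (ys[e] == 1L) "cough" else "noncough"
        extract_training_windows(
          label_track(at / sr, (at + n_ev) / sr, lab), a, config,
          participant_id = sprintf("p%02d", i), night_id = sprintf("p%02d_n1", i),
          cough_offsets = runif(1, -cough_jitter, cough_jitter),
          shoulder_offsets = if (is.null(shoulder_offset)) numeric(0) else
            c(-shoulder_offset, shoulder_offset))
      })
      bind_windows(sets)
    })
    corpus <- bind_windows(parts)
    corpus$sex <- rep(sexes, vapply(parts, function(p) length(p$y), 0L))
    corpus
  })
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, ensemble training on participant-disjunct folds,
#' threshold tuning, per-night segmentation, epoch derivation, sex
#' assignment, and evaluation; returns all reports plus a manifest of seeds
#' and configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, per-night counts (CSV),
#'   metrics (JSON), and the manifest (JSON) are written there.
#' @param stages Stages to execute, a subset of `"recognition"`,
#'   `"segmentation"`, `"sex"`; recognition is always run (the segmentation
#'   stage deploys its ensemble). A stage failure halts with the stage name;
#'   outputs of completed stages are still written when `out_dir` is given.
#' @return List with `recognition`, `segmentation`, `sex` (the latter two
#'   `NULL` when not requested), and `manifest`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL,
                           stages = c("recognition", "segmentation", "sex")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  fc <- config$feature
  at_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## 1. recognition corpus, training, thresholding
  recog <- NULL; model <- NULL; seg_report <- NULL; sex_report <- NULL
  at_stage("recognition", {
    train_corpus <- synth_window_corpus(
      config$n_train_participants, config$events_per_participant$cough,
      config$events_per_participant$noncough, config = fc, seed = seed + 10L)
    test_corpus <- synth_window_corpus(
      config$n_test_participants, config$events_per_participant$cough,
      config$events_per_participant$noncough, config = fc, seed = seed + 20L)
    folds <- make_disjunct_folds(train_corpus, 5L, seed = seed + 30L)
    tc <- config$training
    tc$seed <- seed + 40L
    model <- train_ensemble(folds, tc, config$arch)
    model$threshold <- tune_threshold(model, test_corpus)
    pred <- ensemble_predict(model, test_corpus$x)
    cm <- confusion_counts(as.integer(pred$decision), test_corpus$y)
    recog <- list(threshold = model$threshold, confusion = cm,
                   metrics = confusion_metrics(cm),
                   curves = roc_pr_curves(pred$probability, test_corpus$y))
  })

  ## 2. segmentation: calibrate the threshold on validation nights, then
  ## evaluate on fresh nights
  if ("segmentation" %in% stages) at_stage("segmentation", {
    # validation nights are event-dense: an information-rich calibration
    # recording localizes the count-optimal threshold with few night-hours
    val <- lapply(seq_len(config$n_val_nights), function(i) {
      night <- synth_night(night_config(
        duration = config$night_duration, seed = seed + 300L + i,
        cough_epoch_rate = 30, isolated_cough_rate = 30,
        noncough_event_rate = 90,
        sex = if (i %% 2L) "female" else "male", sample_rate = fc$sample_rate))
      list(series = slide_and_score(night$audio, model, fc),
           count = sum(night$events$label == "cough"))
    })
    model$threshold <- tune_segmentation_threshold(
      lapply(val, function(v) v$series),
      vapply(val, function(v) v$count, integer(1)))
    nights <- lapply(seq_len(config$n_nights), function(i) {
      nc <- night_config(duration = config$night_duration, seed = seed + 100L + i,
                         sex = if (i %% 2L) "female" else "male",
                         sample_rate = fc$sample_rate)
      night <- synth_night(nc)
      seg <- segment_recording(night$audio, model, fc)
      truth_mid <- (night$events$start + night$events$end)[night$events$label == "cough"] / 2
      truth_ep <- derive_epochs(sort(truth_mid))
      data.frame(night_id = i,
                 automated_count = seg$cough_count,
                 annotated_count = sum(night$events$label == "cough"),
                 automated_epochs = seg$epoch_count,
                 annotated_epochs = truth_ep$epoch_count)
    })
    nights <- do.call(rbind, nights)
    seg_report <- list(
      threshold = model$threshold,
      nights = nights,
      cough_ba = bland_altman(nights),
      epoch_ba = bland_altman(data.frame(automated_count = nights$automated_epochs,
                                         annotated_count = nights$annotated_epochs)),
      exact_night_fraction = mean(nights$automated_count == nights$annotated_count)
    )
  })

  ## 3. sex assignment
  if ("sex" %in% stages) at_stage("sex", {
    sex_report <- sex_assignment_experiment(
      n_per_class = config$sex_coughs_per_class, k = config$gmm_k,
      n_init = config$gmm_n_init, iterations = config$gmm_iterations,
      sample_rate = fc$sample_rate, seed = seed + 200L)
  })

  manifest <- list(
    seed = seed,
    stage_seeds = list(train_corpus = seed + 10L, test_corpus = seed + 20L,
                       folds = seed + 30L, training = seed + 40L,
                       nights = seed + 101L, sex = seed + 200L),
    arch = list(channels = config$arch$channels),
    training = unclass(config$training),
    feature = unclass(config$feature)
  )
  res <- list(recognition = recog, segmentation = seg_report,
              sex = sex_report, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    metrics <- list(recognition = recog$metrics, threshold = recog$threshold,
                    roc_auc = recog$curves$roc_auc, pr_auc = recog$curves$pr_auc)
    if (!is.null(seg_report)) {
      utils::write.csv(seg_report$nights, file.path(out_dir, "night_counts.csv"),
                       row.names = FALSE)
      metrics$cough_bland_altman <-
        seg_report$cough_ba[c("mean_diff", "lower_limit", "upper_limit")]
      metrics$exact_night_fraction <- seg_report$exact_night_fraction
    }
    if (!is.null(sex_report)) {
      metrics$sex_accuracy_cough <- sex_report$cough_accuracy
      metrics$sex_accuracy_epoch <- sex_report$epoch_accuracy
    }
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Train and evaluate GMM sex assignment on a synthetic cough corpus
#'
#' Generates sexed coughs for disjoint synthetic participants, splits them
#' participant-disjunct, fits per-sex GMMs on training coughs, and evaluates
#' cough-level and epoch-level (concatenated consecutive coughs of one
#' participant) classification accuracy, with female as the positive class.
#'
#' @param n_per_class Training+test coughs per sex.
#' @param n_participants_per_class Synthetic participants per sex.
#' @param coughs_per_epoch Coughs concatenated per synthetic epoch.
#' @param k,n_init,iterations GMM hyperparameters.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return List with the fitted model, per-level accuracies, confusion
#'   metrics, and ROC areas.
#' @export
sex_assignment_experiment <- function(n_per_class = 120L,
                                      n_participants_per_class = 12L,
                                      coughs_per_epoch = 3L,
                                      k = 30L, n_init = 3L, iterations = 200L,
                                      sample_rate = 22050, seed = 1L) {
  with_seed(seed, {
    make_class <- function(sex) {
      pid <- rep(seq_len(n_participants_per_class), length.out = n_per_class)
      waves <- lapply(seq_len(n_per_class), function(i) {
        spec <- cough_spec(sex, burst_duration = runif(1, 0.3, 0.55),
                           peak_level_db = runif(1, -16, -6))
        synth_cough(spec, sample_rate)$samples
      })
      list(waves = waves, pid = pid)
    }
    fem <- make_class("female"); mal <- make_class("male")
    split_ids <- function(cls) {
      ids <- unique(cls$pid)
      tr <- sample(ids, ceiling(length(ids) / 2))
      list(train = tr, test = setdiff(ids, tr))
    }
    sf <- split_ids(fem); sm <- split_ids(mal)
    feats_of <- function(w) extract_sex_features(audio_segment(w, sample_rate))
    train_f <- lapply(fem$waves[fem$pid %in% sf$train], feats_of)
    train_m <- lapply(mal$waves[mal$pid %in% sm$train], feats_of)
    model <- fit_gmm(train_f, train_m, k = k, n_init = n_init,
                     iterations = iterations, seed = seed)

    classify_all <- function(feat_list) {
      vapply(feat_list, function(f) classify_sex(f, model)$label, character(1))
    }
    margin_all <- function(feat_list) {
      vapply(feat_list, function(f) classify_sex(f, model)$margin, numeric(1))
    }
    test_f <- lapply(fem$waves[fem$pid %in% sf$test], feats_of)
    test_m <- lapply(mal$waves[mal$pid %in% sm$test], feats_of)
    pred <- c(classify_all(test_f), classify_all(test_m))
    truth <- c(rep("female", length(test_f)), rep("male", length(test_m)))
    cough_acc <- mean(pred == truth)
    cm <- confusion_counts(as.integer(pred == "female"), as.integer(truth == "female"))

    # epoch level: concatenate consecutive same-participant test coughs
    concat_epochs <- function(cls, ids) {
      keep <- which(cls$pid %in% ids)
      groups <- split(keep, ceiling(seq_along(keep) / coughs_per_epoch))
      groups <- groups[lengths(groups) >= 2L]
      lapply(groups, function(g) {
        feats_of(unlist(cls$waves[g]))
      })
    }
    ep_f <- concat_epochs(fem, sf$test); ep_m <- concat_epochs(mal, sm$test)
    ep_pred <- c(classify_all(ep_f), classify_all(ep_m))
    ep_truth <- c(rep("female", length(ep_f)), rep("male", length(ep_m)))
    epoch_acc <- mean(ep_pred == ep_truth)
    scores <- c(margin_all(test_f), margin_all(test_m))
    list(model = model, cough_accuracy = cough_acc, epoch_accuracy = epoch_acc,
         cough_metrics = confusion_metrics(cm),
         roc = roc_pr_curves(scores, as.integer(truth == "female")))
  })
}
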