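#' Annotation label track
#'
#' An ordered table of annotated acoustic events, as produced by Audacity
#' label tracks: each event has a start and end time (seconds) and a label.
#' Labels are free-form strings; the pipeline uses `cough`, `noncough` (or
#' `noncough:<kind>`), `uncertain`, and `silence`/`sound`.
#'
#' @param start,end Numeric vectors of event boundaries in seconds
#'   (`start < end` element-wise).
#' @param label Character vector of labels.
#' @return A `label_track`: a data frame with columns `start`, `end`, `label`,
#'   sorted by `start`.
#' @export
label_track <- function(start = numeric(), end = numeric(), label = character()) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  start <- as.numeric(start); end <- as.numeric(end); label <- as.character(label)
  bad <- which(end <= start)
  if (length(bad)) stopf("event %d has end <= start (%.6f <= %.6f)", bad[1], end[bad[1]], start[bad[1]])
  o <- order(start, end)
  structure(
    data.frame(start = start[o], end = end[o], label = label[o], stringsAsFactors = FALSE),
    class = c("label_track", "data.frame")
  )
}

#' Read an Audacity label track (TSV)
#'
#' Expects 3 tab-separated columns: start, end, label. Events are returned
#' sorted by start time; malformed rows raise an error naming the line.
#'
#' @param path Path to the TSV file.
#' @return A [label_track()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(label_track())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3L)) {
    stopf("unparseable label row at line %d (need 3 tab-separated fields)", which(n_fields < 3L)[1])
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  lab <- vapply(parts, `[[`, "", 3L)
  if (anyNA(start) || anyNA(end)) {
    stopf("non-numeric time at line %d", which(is.na(start) | is.na(end))[1])
  }
  bad <- which(end <= start)
  if (length(bad)) stopf("end <= start at line %d", bad[1])
  label_track(start, end, lab)
}

#' Write an Audacity label track (TSV)
#'
#' Times are written with 6 decimals (microsecond resolution).
#'
#' @param path Output path.
#' @param labels A [label_track()].
#' @return `path`, invisibly.
#' @export
write_labels <- function(path, labels) {
  lines <- sprintf("%.6f\t%.6f\t%s", labels$start, labels$end, labels$label)
  writeLines(lines, path)
  invisible(path)
}

#' Mark silence with an amplitude-threshold filter
#'
#' Reproduces a Sound Finder style silence detector: the recording is scanned
#' in short RMS frames (10 ms, 50% overlap); a contiguous stretch whose frames
#' all fall below `threshold_db` (dB relative to full scale) is labeled
#' `silence` only if it lasts at least `min_silence` seconds. All remaining
#' time is labeled `sound`. The returned intervals partition the recording
#' exactly; interval edges are snapped to frame boundaries.
#'
#' @param audio An [audio_segment()].
#' @param threshold_db Silence threshold in dBFS (must be < 0); default -26.
#' @param min_silence Minimum silence duration in seconds; default 1.0.
#' @param frame_dur RMS frame duration in seconds (default 0.010, hop half).
#' @return A [label_track()] of alternating `silence` / `sound` intervals.
#' @export
mark_silence <- function(audio, threshold_db = -26, min_silence = 1.0, frame_dur = 0.010) {
  stopifnot(inherits(audio, "audio_segment"))
  if (threshold_db >= 0) stopf("threshold_db must be negative (dBFS), got %g", threshold_db)
  n <- length(audio$samples)
  if (n == 0L) stopf("empty audio")
  sr <- audio$sample_rate
  dur <- n / sr
  flen <- max(1L, round(frame_dur * sr))
  hop <- max(1L, flen %/% 2L)
  starts <- seq(1L, n, by = hop)
  # frame RMS in dBFS; last frames shrink at the edge
  rms_db <- vapply(starts, function(s) {
    e <- min(n, s + flen - 1L)
    amp_to_db(sqrt(mean(audio$samples[s:e]^2)))
  }, numeric(1))
  quiet <- rms_db < threshold_db

  # hop-grid cell k covers [ (k-1)*hop, k*hop ) seconds; cell quiet iff its frame is quiet
  r <- rle(quiet)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  cell_t <- function(i) min(dur, (i - 1L) * hop / sr)
  sil_start <- numeric(); sil_end <- numeric()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    t0 <- cell_t(starts_idx[j])
    t1 <- if (ends_idx[j] >= length(starts)) dur else cell_t(ends_idx[j] + 1L)
    if (t1 - t0 >= min_silence) {
      sil_start <- c(sil_start, t0); sil_end <- c(sil_end, t1)
    }
  }
  # complement = sound; together they partition [0, dur]
  s_start <- numeric(); s_end <- numeric()
  cur <- 0
  for (j in seq_along(sil_start)) {
    if (sil_start[j] > cur) { s_start <- c(s_start, cur); s_end <- c(s_end, sil_start[j]) }
    cur <- sil_end[j]
  }
  if (cur < dur) { s_start <- c(s_start, cur); s_end <- c(s_end, dur) }
  label_track(
    c(sil_start, s_start), c(sil_end, s_end),
    c(rep("silence", length(sil_start)), rep("sound", length(s_start)))
  )
}
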