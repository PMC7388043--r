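# Independent brute-force implementations used as oracles in the
# equivalence tests. Written to be obviously correct, not fast.

# Build a probability_series by hand (as slide_and_score would).
make_series <- function(probability, stride = 0.065, window = 0.650,
                        silent = rep(FALSE, length(probability))) {
  structure(
    data.frame(time = (seq_along(probability) - 1) * stride,
               probability = probability, silent = silent),
    class = c("probability_series", "data.frame"),
    stride = stride, window = window
  )
}

# Scan-based postprocessing oracle: explicit state machine over windows.
oracle_postprocess <- function(series, threshold, max_run = 8L, rule2_level = 0.9) {
  p <- series$probability
  stride <- attr(series, "stride")
  window <- attr(series, "window")
  n <- length(p)
  above <- p >= threshold
  times <- numeric()
  center <- function(i0, i1) {
    (series$time[i0] + (series$time[i1] + window)) / 2
  }
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && above[j + 1L]) j <- j + 1L
    len <- j - i + 1L
    if (len == 1L) {
      if (i < n && (p[i] + p[i + 1L]) / 2 > rule2_level) times <- c(times, center(i, i))
    } else if (len <= max_run) {
      times <- c(times, center(i, j))
    } else {
      half1 <- floor(len / 2)
      times <- c(times, center(i, i + half1 - 1L), center(i + half1, j))
    }
    i <- j + 1L
  }
  times
}

# Epoch oracle: explicit pairwise grouping.
oracle_epochs <- function(times, pause = 2.0) {
  n <- length(times)
  if (n == 0L) return(list(count = 0L, coughs = 0L))
  group <- integer(n); group[1] <- 1L
  for (i in seq_len(n - 1L)) {
    group[i + 1L] <- if (times[i + 1L] - times[i] < pause) group[i] else group[i] + 1L
  }
  sizes <- table(group)
  keep <- sizes[sizes >= 2L]
  list(count = length(keep), coughs = sum(keep))
}

# Confusion-metric oracle straight from the definitions.
oracle_metrics <- function(tp, fp, fn, tn) {
  dv <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    sensitivity = dv(tp, tp + fn),
    specificity = dv(tn, tn + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    mcc = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
    },
    ppv = dv(tp, tp + fp),
    npv = dv(tn, tn + fn)
  )
}

# Quadratic ROC/PR oracle: evaluate every distinct threshold explicitly.
oracle_roc_pr <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tpr <- fpr <- rec <- prec <- numeric(length(ts))
  for (i in seq_along(ts)) {
    pred <- scores >= ts[i]
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    tpr[i] <- tp / n_pos; fpr[i] <- fp / n_neg
    rec[i] <- tp / n_pos; prec[i] <- tp / (tp + fp)
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(roc_auc = trap(c(0, fpr), c(0, tpr)),
       pr_auc = trap(c(0, rec), c(prec[1], prec)))
}

oracle_bland_altman <- function(auto, annot) {
  d <- auto - annot
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(mean_diff = m, lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s)
}
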