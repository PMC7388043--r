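# Sex assignment of cough / cough-epoch signals with per-sex Gaussian
# mixture models over the 41-row MFCC/delta/delta-ZCR representation.
#
# Each class (female, male) is modeled as a K-component mixture with
# diagonal covariances, fitted by expectation-maximization from k-means
# seeding; classification compares total log-likelihoods under equal priors.

# log-density of each row of x (n x d) under each diagonal component:
# returns n x K matrix of log N(x | mu_k, diag(var_k)) + log w_k
diag_gmm_logcomp <- function(x, means, vars, weights) {
  d <- ncol(x)
  # quadratic form expands to x^2 . (1/2v) - x . (mu/v) + const_k
  inv2v <- t(1 / (2 * vars))                   # d x K
  mu_over_v <- t(means / vars)                 # d x K
  const_k <- -0.5 * (d * log(2 * pi) + rowSums(log(vars)) + rowSums(means^2 / vars))
  q <- (x^2) %*% inv2v - x %*% mu_over_v       # n x K, missing sign/consts
  sweep(-q, 2L, const_k + log(weights), `+`)
}

# one EM run from a k-means seeding; returns fit with loglik trace
em_diag_gmm <- function(x, k, iterations, seed, var_floor = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  with_seed(seed, {
    init <- tryCatch(
      stats::kmeans(x, centers = k, iter.max = 10L, nstart = 1L),
      error = function(e) NULL
    )
    if (!is.null(init) && length(unique(init$cluster)) == k) {
      means <- init$centers
      weights <- as.numeric(table(factor(init$cluster, levels = seq_len(k)))) / n
      vars <- matrix(0, k, d)
      gv <- apply(x, 2L, stats::var)
      for (j in seq_len(k)) {
        xs <- x[init$cluster == j, , drop = FALSE]
        vars[j, ] <- if (nrow(xs) > 1L) apply(xs, 2L, stats::var) else gv
      }
    } else {
      means <- x[sample(n, k), , drop = FALSE]
      weights <- rep(1 / k, k)
      vars <- matrix(apply(x, 2L, stats::var), k, d, byrow = TRUE)
    }
    vars <- pmax(vars, var_floor)
    weights <- pmax(weights, 1e-12); weights <- weights / sum(weights)

    loglik <- numeric(iterations)
    for (it in seq_len(iterations)) {
      lc <- diag_gmm_logcomp(x, means, vars, weights)
      lse <- row_logsumexp(lc)
      loglik[it] <- sum(lse)
      resp <- exp(lc - lse)                    # n x K responsibilities
      nk <- colSums(resp)
      nk <- pmax(nk, 1e-12)
      weights <- nk / n
      means <- (t(resp) %*% x) / nk
      ex2 <- (t(resp) %*% (x^2)) / nk
      vars <- pmax(ex2 - means^2, var_floor)
    }
    list(means = means, vars = vars, weights = weights, loglik = loglik)
  })
}

#' Fit per-sex diagonal-covariance Gaussian mixture models
#'
#' For each class, EM is run `n_init` times from distinct k-means seedings
#' and the fit with the best final log-likelihood is retained. Variances are
#' floored at `var_floor` to prevent singular components.
#'
#' @param female,male Lists of `sex_features` matrices (41 x F each); frames
#'   are pooled per class.
#' @param k Number of mixture components per class (default 30).
#' @param n_init Number of EM initializations (default 3).
#' @param iterations EM iterations per run (default 200).
#' @param seed Integer seed.
#' @param var_floor Lower bound on covariance diagonals.
#' @return A `gmm_sex_model` with per-class components and fit metadata
#'   (including the retained run's log-likelihood trace).
#' @export
fit_gmm <- function(female, male, k = 30L, n_init = 3L, iterations = 200L,
                    seed = 1L, var_floor = 1e-6) {
  fit_class <- function(feats, class_seed) {
    x <- t(do.call(cbind, feats))              # frames as rows
    if (nrow(x) < k) stopf("class has %d frames, fewer than K = %d", nrow(x), k)
    runs <- lapply(seq_len(n_init), function(i) {
      em_diag_gmm(x, k, iterations, seed = class_seed + i, var_floor = var_floor)
    })
    finals <- vapply(runs, function(r) r$loglik[iterations], numeric(1))
    runs[[which.max(finals)]]
  }
  structure(list(
    female = fit_class(if (is.list(female)) female else list(female), seed),
    male = fit_class(if (is.list(male)) male else list(male), seed + 1000L),
    k = as.integer(k), n_init = as.integer(n_init),
    iterations = as.integer(iterations)
  ), class = "gmm_sex_model")
}

# total log-likelihood of a feature matrix (41 x F) under one class fit
gmm_class_loglik <- function(feats, fit) {
  x <- t(feats)
  sum(row_logsumexp(diag_gmm_logcomp(x, fit$means, fit$vars, fit$weights)))
}

#' Assign sex to a cough or cough-epoch signal
#'
#' Per-frame log-likelihoods are summed over frames for each class and
#' compared under equal priors; the label is the class with the larger total.
#' An exact tie returns `female` with `tie = TRUE`.
#'
#' @param x A `sex_features` matrix (41 rows).
#' @param model A `gmm_sex_model`.
#' @return List with `label`, `margin` (female minus male total
#'   log-likelihood), and `tie`.
#' @export
classify_sex <- function(x, model) {
  stopifnot(inherits(model, "gmm_sex_model"))
  if (nrow(x) != ncol(model$female$means)) {
    stopf("feature matrix has %d rows; model expects %d", nrow(x), ncol(model$female$means))
  }
  llf <- gmm_class_loglik(x, model$female)
  llm <- gmm_class_loglik(x, model$male)
  if (!is.finite(llf) || !is.finite(llm)) stopf("non-finite log-likelihood")
  margin <- llf - llm
  list(label = if (margin >= 0) "female" else "male", margin = margin,
       tie = margin == 0)
}

#' Participant-disjunct train/test split for sex classification
#'
#' Honors requested per-sex participant counts (default: 10 female + 9 male
#' train, 9 female + 10 male test); only participants flagged as having
#' slept alone are eligible.
#'
#' @param participants Data frame with columns `id`, `sex`
#'   (`"female"`/`"male"`), and optionally `slept_alone` (logical).
#' @param seed Integer seed.
#' @param train_female,train_male,test_female,test_male Per-sex counts.
#' @return List with `train` and `test` data frames.
#' @export
partition_sex_dataset <- function(participants, seed = 1L,
                                  train_female = 10L, train_male = 9L,
                                  test_female = 9L, test_male = 10L) {
  if (!is.null(participants$slept_alone)) {
    participants <- participants[participants$slept_alone, , drop = FALSE]
  }
  f <- participants$id[participants$sex == "female"]
  m <- participants$id[participants$sex == "male"]
  if (length(f) < train_female + test_female) {
    stopf("need %d female participants, have %d", train_female + test_female, length(f))
  }
  if (length(m) < train_male + test_male) {
    stopf("need %d male participants, have %d", train_male + test_male, length(m))
  }
  with_seed(seed, {
    f <- sample(f); m <- sample(m)
    train_ids <- c(f[seq_len(train_female)], m[seq_len(train_male)])
    test_ids <- c(f[train_female + seq_len(test_female)],
                  m[train_male + seq_len(test_male)])
    list(train = participants[participants$id %in% train_ids, , drop = FALSE],
         test = participants[participants$id %in% test_ids, , drop = FALSE])
  })
}
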