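test_that("component log-densities match sums of univariate normals", {
  set.seed(13)
  n <- 20L; d <- 4L; k <- 3L
  x <- matrix(rnorm(n * d), n)
  means <- matrix(rnorm(k * d), k)
  vars <- matrix(runif(k * d, 0.5, 2), k)
  w <- c(0.2, 0.3, 0.5)
  lc <- nightcough:::diag_gmm_logcomp(x, means, vars, w)
  for (i in 1:n) for (j in 1:k) {
    direct <- sum(dnorm(x[i, ], means[j, ], sqrt(vars[j, ]), log = TRUE)) + log(w[j])
    expect_equal(lc[i, j], direct, tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is non-decreasing on mixture data", {
  set.seed(14)
  x <- rbind(matrix(rnorm(200, -2), ncol = 2), matrix(rnorm(200, 2), ncol = 2))
  fit <- nightcough:::em_diag_gmm(x, k = 3L, iterations = 60L, seed = 5L)
  expect_length(fit$loglik, 60L)
  expect_true(all(diff(fit$loglik) >= -1e-7))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$vars >= 1e-6))
})

test_that("K = 1 EM recovers the maximum-likelihood mean and variance", {
  set.seed(15)
  x <- matrix(rnorm(3000, mean = c(1, -2, 0.5), sd = c(1, 0.5, 2)),
              ncol = 3, byrow = TRUE)
  fit <- nightcough:::em_diag_gmm(x, k = 1L, iterations = 5L, seed = 1L)
  expect_equal(drop(fit$means), colMeans(x), tolerance = 1e-10)
  mle_var <- colMeans(x^2) - colMeans(x)^2
  expect_equal(drop(fit$vars), mle_var, tolerance = 1e-10)
  expect_equal(unname(drop(fit$weights)), 1)
})

test_that("fit_gmm keeps the best of n_init runs and validates sizes", {
  set.seed(16)
  f <- matrix(rnorm(41 * 60, 1), 41)
  m <- matrix(rnorm(41 * 60, -1), 41)
  model <- fit_gmm(f, m, k = 2L, n_init = 2L, iterations = 20L, seed = 3L)
  expect_s3_class(model, "gmm_sex_model")
  expect_equal(dim(model$female$means), c(2L, 41L))
  expect_error(fit_gmm(f[, 1:3], m, k = 5L, n_init = 1L, iterations = 5L),
               "fewer than K")
  # best-of-inits: final loglik at least that of each individual run
  runs <- lapply(1:2, function(i) {
    nightcough:::em_diag_gmm(t(f), 2L, 20L, seed = 3L + i)
  })
  finals <- vapply(runs, function(r) r$loglik[20], numeric(1))
  expect_equal(model$female$loglik[20], max(finals))
})

test_that("classify_sex compares total log-likelihoods with female on ties", {
  set.seed(17)
  f <- matrix(rnorm(41 * 80, 2, 0.5), 41)
  m <- matrix(rnorm(41 * 80, -2, 0.5), 41)
  model <- fit_gmm(f, m, k = 2L, n_init = 1L, iterations = 30L, seed = 1L)
  rf <- classify_sex(matrix(rnorm(41 * 10, 2, 0.5), 41), model)
  rm_ <- classify_sex(matrix(rnorm(41 * 10, -2, 0.5), 41), model)
  expect_equal(rf$label, "female")
  expect_gt(rf$margin, 0)
  expect_equal(rm_$label, "male")
  expect_lt(rm_$margin, 0)
  expect_false(rf$tie)
  # identical class models force an exact tie -> female, flagged
  tied <- model
  tied$male <- tied$female
  rt <- classify_sex(matrix(rnorm(41 * 5), 41), tied)
  expect_equal(rt$label, "female")
  expect_true(rt$tie)
  expect_error(classify_sex(matrix(0, 10, 3), model), "expects 41")
})

test_that("GMM agrees with mclust on a well-separated fit", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(18)
  x <- rbind(matrix(rnorm(300, -4, 0.5), ncol = 3),
             matrix(rnorm(300, 4, 0.5), ncol = 3))
  fit <- nightcough:::em_diag_gmm(x, k = 2L, iterations = 100L, seed = 2L)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  # same total log-likelihood at the (shared, well-separated) optimum
  expect_equal(fit$loglik[100], mc$loglik, tolerance = 1e-4)
  ours <- fit$means[order(fit$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("partition_sex_dataset honors per-sex counts and slept-alone filter", {
  participants <- data.frame(
    id = sprintf("s%02d", 1:60),
    sex = rep(c("female", "male"), each = 30),
    slept_alone = rep(c(rep(TRUE, 25), rep(FALSE, 5)), 2)
  )
  sp <- partition_sex_dataset(participants, seed = 6L)
  expect_equal(sum(sp$train$sex == "female"), 10L)
  expect_equal(sum(sp$train$sex == "male"), 9L)
  expect_equal(sum(sp$test$sex == "female"), 9L)
  expect_equal(sum(sp$test$sex == "male"), 10L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_true(all(c(sp$train$slept_alone, sp$test$slept_alone)))
  few <- participants[1:10, ]
  expect_error(partition_sex_dataset(few), "female participants")
})
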