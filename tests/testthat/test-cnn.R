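naive_conv_same <- function(x3, wmat, b, kh, kw, cout) {
  # direct 'same' stride-1 convolution of an (h, w, cin) volume
  h <- dim(x3)[1]; w <- dim(x3)[2]; cin <- dim(x3)[3]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  xp <- array(0, c(h + 2 * ph, w + 2 * pw, cin))
  xp[ph + 1:h, pw + 1:w, ] <- x3
  out <- array(0, c(h, w, cout))
  for (co in seq_len(cout)) {
    wk <- array(wmat[co, ], c(kh, kw, cin))
    for (i in 1:h) for (j in 1:w) {
      out[i, j, co] <- sum(xp[i:(i + kh - 1), j:(j + kw - 1), ] * wk) + b[co]
    }
  }
  out
}

test_that("conv_forward matches a direct convolution", {
  set.seed(11)
  h <- 5L; w <- 6L; cin <- 2L; cout <- 3L; kh <- 3L; kw <- 3L; n <- 2L
  x4 <- array(rnorm(h * w * cin * n), c(h, w, cin, n))
  wmat <- matrix(rnorm(cout * kh * kw * cin), cout)
  b <- rnorm(cout)
  got <- nightcough:::conv_forward(x4, wmat, b, kh, kw)$out
  for (s in 1:n) {
    expect_equal(got[, , , s], naive_conv_same(x4[, , , s], wmat, b, kh, kw, cout),
                 tolerance = 1e-12)
  }
})

test_that("ceil-mode 2x2 max pooling matches a direct computation", {
  set.seed(12)
  x4 <- array(rnorm(5 * 7 * 2 * 2), c(5, 7, 2, 2))
  got <- nightcough:::pool_forward(x4)$out
  expect_equal(dim(got), c(3L, 4L, 2L, 2L))
  for (s in 1:2) for (c in 1:2) for (i in 1:3) for (j in 1:4) {
    ri <- (2 * i - 1):min(5, 2 * i)
    rj <- (2 * j - 1):min(7, 2 * j)
    expect_equal(got[i, j, c, s], max(x4[ri, rj, c, s]))
  }
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- tiny_arch()
  model <- init_cnn(arch, seed = 21L)
  set.seed(22)
  n <- 3L
  x4 <- array(rnorm(12 * 16 * 1 * n, sd = 0.5), c(12L, 16L, 1L, n))
  y <- c(1, 0, 1)
  loss_of <- function(m) {
    fwd <- nightcough:::cnn_forward(m, x4, train = TRUE)
    nightcough:::bce_loss(fwd$prob, y)
  }
  fwd <- nightcough:::cnn_forward(model, x4, train = TRUE)
  grads <- nightcough:::cnn_backward(model, fwd, x4, y)
  # cnn_backward uses dz/n (mean loss); check a sample of coordinates in
  # every parameter block against central differences
  eps <- 1e-5
  worst <- 0
  for (nm in names(grads)) {
    p <- model$params[[nm]]
    k <- min(6L, length(p))
    idx <- if (length(p) > k) sample(length(p), k) else seq_along(p)
    for (ii in idx) {
      mp <- model; mp$params[[nm]][ii] <- p[ii] + eps
      mm <- model; mm$params[[nm]][ii] <- p[ii] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      g <- grads[[nm]][ii]
      rel <- abs(fd - g) / max(1e-8, abs(fd) + abs(g))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("predict_cnn is chunk-invariant and deterministic", {
  arch <- tiny_arch()
  model <- init_cnn(arch, seed = 31L)
  set.seed(32)
  x <- array(rnorm(12 * 16 * 7), c(12L, 16L, 7L))
  p1 <- predict_cnn(model, x, chunk = 64L)
  p2 <- predict_cnn(model, x, chunk = 3L)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(length(predict_cnn(model, x[, , 1])), 1L)
})

test_that("init_cnn is reproducible and Xavier-bounded", {
  arch <- tiny_arch()
  m1 <- init_cnn(arch, seed = 7L)
  m2 <- init_cnn(arch, seed = 7L)
  expect_identical(m1$params, m2$params)
  d <- arch$dims[[1]]
  lim <- sqrt(6 / (d$kh * d$kw * d$cin + d$kh * d$kw * d$cout))
  expect_true(all(abs(m1$params$W1) <= lim))
  expect_equal(m1$params$b1, numeric(d$cout))
})

test_that("train_member memorizes a small separable set and is reproducible", {
  arch <- tiny_arch()
  set.seed(41)
  n <- 12L
  x <- array(0, c(12L, 16L, n))
  y <- rep(c(1L, 0L), each = n / 2)
  # class 1: energy in top rows; class 0: energy in bottom rows
  for (i in 1:n) {
    r <- if (y[i] == 1L) 1:6 else 7:12
    x[r, , i] <- rnorm(6 * 16, mean = 1, sd = 0.2)
  }
  fold <- list(x = x, y = y)
  cfg <- training_config(iterations = 80L, batch_size = 8L, seed = 5L)
  model <- train_member(fold, cfg, arch)
  trace <- attr(model, "loss_trace")
  expect_equal(length(trace), 80L)
  expect_lt(mean(tail(trace, 10)), mean(head(trace, 10)))
  p <- predict_cnn(model, x)
  expect_true(all((p >= 0.5) == (y == 1L)))
  model2 <- train_member(fold, cfg, arch)
  expect_identical(model$params, model2$params)
})

test_that("training_config and cnn_architecture validate input", {
  expect_error(training_config(batch_size = 7L), "even")
  expect_error(cnn_architecture(kernels = list(c(2L, 7L), c(7L, 1L), c(3L, 3L),
                                               c(3L, 3L), c(3L, 3L))), "odd")
  desk <- cnn_architecture(desk = TRUE)
  expect_equal(desk$channels, c(8L, 12L, 12L, 16L, 16L))
  expect_equal(cnn_architecture()$channels, c(16L, 32L, 32L, 64L, 64L))
})
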