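test_that("power-sigmoid is odd, increasing, continuous, with exact anchors", {
  for (ab in list(c(3, 3), c(5, 4), c(7, 5))) {
    a <- ab[1]; b <- ab[2]
    expect_equal(power_sigmoid(1, a, b), 1)
    expect_equal(power_sigmoid(-1, a, b), -1)
    grid <- seq(-2.5, 2.5, by = 0.01)
    y <- power_sigmoid(grid, a, b)
    expect_equal(y, -rev(power_sigmoid(rev(-grid), a, b)))  # odd
    expect_true(all(diff(y) > 0))                            # increasing
    # continuity at the branch point
    eps <- 1e-9
    expect_lt(abs(power_sigmoid(1 - eps, a, b) - power_sigmoid(1 + eps, a, b)),
              1e-6)
  }
  expect_equal(power_sigmoid(2, alpha = 3, beta = 3), 8)
  direct <- (1 + exp(-3)) * (1 - exp(-1.5)) / ((1 - exp(-3)) * (1 + exp(-1.5)))
  expect_equal(power_sigmoid(0.5, alpha = 3, beta = 3), direct,
               tolerance = 1e-12)
  expect_error(power_sigmoid(1, alpha = 4, beta = 3), "odd")
  expect_error(power_sigmoid(1, alpha = 3, beta = 2), "beta")
})

test_that("rnn_step matches its scalar expansion and structural limits", {
  set.seed(301)
  for (trial in 1:20) {
    p <- random_rnn_params(2L, 3L)
    x <- rnorm(3); h0 <- rnorm(2) * 0.4
    got <- rnn_step(x, h0, p)
    ref <- rnn_step_oracle(x, h0, p)
    expect_equal(got$h, ref$h, tolerance = 1e-10)
    expect_equal(got$y, ref$y, tolerance = 1e-10)
  }
  # zero weights and biases: sigma(0) = 0 everywhere
  p0 <- list(W_ih = matrix(0, 2, 3), W_h = matrix(0, 2, 2), b_h = rep(0, 2),
             W_ho = matrix(0, 4, 2), b_o = rep(0, 4), alpha = 3L, beta = 3)
  st <- rnn_step(rnorm(3), rnorm(2), p0)
  expect_equal(st$h, rep(0, 2))
  expect_equal(st$y, rep(0, 4))
  # W_h = 0 makes h independent of the previous state
  p1 <- random_rnn_params(2L, 3L); p1$W_h <- matrix(0, 2, 2)
  x <- rnorm(3)
  expect_equal(rnn_step(x, rnorm(2), p1)$h, rnn_step(x, rnorm(2), p1)$h)
  expect_error(rnn_step(rnorm(5), rnorm(2), p1), "shape")
})

test_that("gru_step matches its scalar expansion and the u_t limits", {
  set.seed(302)
  for (trial in 1:20) {
    p <- random_gru_params(2L, 3L)
    x <- rnorm(3); h0 <- rnorm(2) * 0.4
    expect_equal(gru_step(x, h0, p), gru_step_oracle(x, h0, p),
                 tolerance = 1e-10)
  }
  # u -> 0 freezes the state; u -> 1 replaces it with the candidate
  # (positive inputs so a constant-sign W_u pins the gate)
  p <- random_gru_params(2L, 3L)
  x <- runif(3) + 0.1; h0 <- runif(2) + 0.1
  p0 <- p; p0$W_u <- matrix(-50, 2, 5)   # sigmoid ~ 0
  expect_equal(gru_step(x, h0, p0), h0, tolerance = 1e-8)
  p1 <- p; p1$W_u <- matrix(50, 2, 5)    # sigmoid ~ 1
  u1 <- gru_step(x, h0, p1)
  r <- 1 / (1 + exp(-as.vector(p1$W_r %*% c(h0, x))))
  hh_ref <- tanh(as.vector(p1$W_hhat %*% c(r * h0, x)))
  expect_equal(u1, hh_ref, tolerance = 1e-8)
  expect_error(gru_step(rnorm(4), h0, p), "shape")
})

test_that("lstm_step matches its scalar expansion and the gate limits", {
  set.seed(303)
  for (trial in 1:20) {
    p <- random_lstm_params(2L, 3L)
    x <- rnorm(3); h0 <- rnorm(2) * 0.4; c0 <- rnorm(2) * 0.4
    got <- lstm_step(x, h0, c0, p)
    ref <- lstm_step_oracle(x, h0, c0, p)
    expect_equal(got$h, ref$h, tolerance = 1e-10)
    expect_equal(got$c, ref$c, tolerance = 1e-10)
  }
  p <- random_lstm_params(2L, 3L)
  x <- rnorm(3); h0 <- rnorm(2); c0 <- rnorm(2)
  # f -> 1, i -> 0: the cell state is carried through unchanged
  pf <- p
  pf$w_fx <- matrix(50, 2, 3); pf$w_fh <- matrix(0, 2, 2)
  pf$w_ix <- matrix(-50, 2, 3); pf$w_ih <- matrix(0, 2, 2)
  expect_equal(lstm_step(abs(x) + 0.1, h0, c0, pf)$c, c0, tolerance = 1e-6)
  # o -> 0: hidden output vanishes
  po <- p; po$w_ox <- matrix(-50, 2, 3); po$w_oh <- matrix(0, 2, 2)
  expect_equal(lstm_step(abs(x) + 0.1, h0, c0, po)$h, rep(0, 2),
               tolerance = 1e-6)
  expect_error(lstm_step(rnorm(4), h0, c0, p), "shape")
})

test_that("gate activations stay in their open intervals", {
  set.seed(304)
  for (trial in 1:25) {
    p <- random_gru_params(3L, 4L)
    x <- rnorm(4); h0 <- rnorm(3)
    cat1 <- c(h0, x)
    u <- 1 / (1 + exp(-as.vector(p$W_u %*% cat1)))
    r <- 1 / (1 + exp(-as.vector(p$W_r %*% cat1)))
    expect_true(all(u > 0 & u < 1))
    expect_true(all(r > 0 & r < 1))
    hh <- tanh(as.vector(p$W_hhat %*% c(r * h0, x)))
    expect_true(all(hh > -1 & hh < 1))
    pl <- random_lstm_params(3L, 4L)
    st <- lstm_step(x, h0, rnorm(3), pl)
    expect_true(all(abs(st$h) < 1))     # |o * tanh(C)| < 1
  }
})

test_that("analytic gradients agree with finite differences for every cell", {
  for (cell in c("rnn", "gru", "lstm")) {
    set.seed(305)
    K <- 2L
    m <- horizon_classifier(cell, 4L, hidden = 3L, n_horizons = K,
                            window = 3L, seed = 5L)
    n <- 6L
    feats <- matrix(rnorm(n * 4), n, 4)
    labels <- matrix(sample(0:2, n * K, TRUE), n, K)
    xs <- ecgfusion:::build_windows(feats, rep("r", n), 3L)
    fwd <- ecgfusion:::hc_forward(m, xs)
    sm <- ecgfusion:::softmax_loss(fwd$z, labels, K)
    gr <- ecgfusion:::hc_backward(m, xs, fwd, sm$dz)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      f <- ecgfusion:::hc_forward(m2, xs)
      ecgfusion:::softmax_loss(f$z, labels, K)$loss
    }
    for (nm in names(gr)) {
      for (idx in seq_len(min(length(m$params[[nm]]), 4L))) {
        eps <- 1e-6
        pp <- m$params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
        l1 <- loss_at(pp)
        pp[[nm]][idx] <- pp[[nm]][idx] - 2 * eps
        l0 <- loss_at(pp)
        expect_equal(gr[[nm]][idx], (l1 - l0) / (2 * eps), tolerance = 1e-5)
      }
    }
  }
})

test_that("training is deterministic, monotone on a smoothed window, and a no-op at 0 epochs", {
  fset <- separable_fset()
  m0 <- horizon_classifier("gru", 6L, hidden = 6L, n_horizons = 1L,
                           window = 1L, seed = 3L)
  z <- hc_train(m0, fset, epochs = 0L)
  expect_identical(z$params, m0$params)
  m1 <- hc_train(m0, fset, epochs = 15L, learning_rate = 0.1)
  m2 <- hc_train(m0, fset, epochs = 15L, learning_rate = 0.1)
  expect_identical(m1$params, m2$params)
  tr <- m1$loss_trace
  expect_lt(mean(utils::tail(tr, 3)), mean(utils::head(tr, 3)))
  # single-class data trains with a warning
  one <- separable_fset()
  one$labels[] <- 1L
  expect_warning(hc_train(m0, one, epochs = 1L), "single class")
})

test_that("all three cells fit the linearly separable fixture", {
  fset <- separable_fset()
  for (cell in c("rnn", "gru", "lstm")) {
    m <- horizon_classifier(cell, 6L, hidden = 6L, n_horizons = 1L,
                            window = 1L, seed = 3L)
    m <- hc_train(m, fset, epochs = 60L, learning_rate = 0.2,
                  batch_size = 30L)
    pr <- hc_predict(m, fset)
    acc <- mean(pr$classes[, 1] == fset$labels[, 1])
    expect_gte(acc, 0.95)
  }
})

test_that("prediction scores are simplex-normalized with lowest-id tie-break", {
  fset <- separable_fset()
  m <- horizon_classifier("rnn", 6L, hidden = 4L, n_horizons = 1L,
                          window = 1L, seed = 9L)
  m <- hc_train(m, fset, epochs = 2L, learning_rate = 0.05)
  pr <- hc_predict(m, fset)
  sums <- apply(pr$scores, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # uniform logits (zeroed readout) tie-break to class 0
  m$params$W_ho[] <- 0; m$params$b_o[] <- 0
  pr0 <- hc_predict(m, fset)
  expect_true(all(pr0$classes == 0L))
  expect_error(hc_predict(horizon_classifier("rnn", 6L, n_horizons = 1L),
                          fset), "untrained")
})

test_that("window length 1 reduces each cell to its feedforward map", {
  set.seed(306)
  feats <- matrix(rnorm(5 * 4), 5, 4)
  m <- horizon_classifier("rnn", 4L, hidden = 3L, n_horizons = 2L,
                          window = 1L, seed = 11L)
  m$scale <- list(mu = rep(0, 4), sd = rep(1, 4))
  m$trained <- TRUE
  fwd <- ecgfusion:::hc_forward(m, list(feats))
  for (i in 1:5) {
    st <- rnn_step(feats[i, ], rep(0, 3), m$params)
    expect_equal(unname(fwd$z[i, ]), unname(st$y), tolerance = 1e-12)
  }
  mg <- horizon_classifier("gru", 4L, hidden = 3L, n_horizons = 2L,
                           window = 1L, seed = 12L)
  fg <- ecgfusion:::hc_forward(mg, list(feats))
  for (i in 1:5) {
    h <- gru_step(feats[i, ], rep(0, 3), mg$params)
    z <- as.vector(mg$params$W_out %*% h) + mg$params$b_out
    expect_equal(unname(fg$z[i, ]), unname(z), tolerance = 1e-12)
  }
})

test_that("models serialize to JSON and back without behavioral change", {
  fset <- separable_fset()
  m <- horizon_classifier("lstm", 6L, hidden = 4L, n_horizons = 1L,
                          window = 2L, seed = 21L)
  m <- hc_train(m, fset, epochs = 4L, learning_rate = 0.1)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  p1 <- hc_predict(m, fset)
  p2 <- hc_predict(back, fset)
  expect_identical(p1$classes, p2$classes)
})
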