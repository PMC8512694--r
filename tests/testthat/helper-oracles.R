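# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (double loops, O(n^2) scans) so they cannot share a
# code path with the implementation they check.

conv_oracle <- function(a, b) {
  L <- length(a)
  out <- numeric(2L * L - 1L)
  for (n in seq_len(2L * L - 1L)) {
    for (k in seq_len(L)) {
      j <- n - k + 1L
      if (j >= 1L && j <= L) out[n] <- out[n] + a[k] * b[j]
    }
  }
  out
}

xcorr_oracle <- function(a, b) {
  L <- length(a)
  vapply(-(L - 1L):(L - 1L), function(k) {
    s <- 0
    for (n in seq_len(L)) {
      j <- n + k
      if (j >= 1L && j <= L) s <- s + a[n] * b[j]
    }
    s
  }, numeric(1))
}

# O(n^2) pairwise-dominance front sorter (minimization).
fronts_oracle <- function(objs) {
  n <- nrow(objs)
  dominated_by <- function(i, j)  # does j dominate i?
    all(objs[j, ] <= objs[i, ]) && any(objs[j, ] < objs[i, ])
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) j != i && dominated_by(i, j),
                  logical(1))), logical(1))]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Scalar (loop-based) expansions of the three cell equations.
sigmoid_scalar <- function(v) 1 / (1 + exp(-v))

psig_scalar <- function(x, alpha, beta) {
  if (abs(x) >= 1) return(x^alpha)
  (1 + exp(-beta)) * (1 - exp(-beta * x)) /
    ((1 - exp(-beta)) * (1 + exp(-beta * x)))
}

rnn_step_oracle <- function(x, h0, p) {
  H <- length(h0)
  h <- vapply(seq_len(H), function(i)
    psig_scalar(sum(p$W_ih[i, ] * x) + sum(p$W_h[i, ] * h0) + p$b_h[i],
                p$alpha, p$beta), numeric(1))
  cc <- (1 + exp(-p$beta)) / (1 - exp(-p$beta))
  y <- vapply(seq_along(p$b_o), function(i)
    cc * tanh(p$beta * (sum(p$W_ho[i, ] * h) + p$b_o[i]) / 2), numeric(1))
  list(h = h, y = y)
}

gru_step_oracle <- function(x, h0, p) {
  H <- length(h0)
  cat1 <- c(h0, x)
  u <- vapply(seq_len(H), function(i)
    sigmoid_scalar(sum(p$W_u[i, ] * cat1)), numeric(1))
  r <- vapply(seq_len(H), function(i)
    sigmoid_scalar(sum(p$W_r[i, ] * cat1)), numeric(1))
  cat2 <- c(r * h0, x)
  hh <- vapply(seq_len(H), function(i)
    tanh(sum(p$W_hhat[i, ] * cat2)), numeric(1))
  (1 - u) * h0 + u * hh
}

lstm_step_oracle <- function(x, h0, c0, p) {
  H <- length(h0)
  gate <- function(wx, wh) vapply(seq_len(H), function(i)
    sigmoid_scalar(sum(wx[i, ] * x) + sum(wh[i, ] * h0)), numeric(1))
  i <- gate(p$w_ix, p$w_ih)
  f <- gate(p$w_fx, p$w_fh)
  o <- gate(p$w_ox, p$w_oh)
  ct <- vapply(seq_len(H), function(k)
    tanh(sum(p$w_cx[k, ] * x) + sum(p$w_ch[k, ] * h0)), numeric(1))
  cc <- f * c0 + i * ct
  list(h = o * tanh(cc), c = cc)
}

random_rnn_params <- function(H, D, O = 6L) {
  list(W_ih = matrix(rnorm(H * D), H, D), W_h = matrix(rnorm(H * H), H, H),
       b_h = rnorm(H), W_ho = matrix(rnorm(O * H), O, H), b_o = rnorm(O),
       alpha = 3L, beta = 3)
}

random_gru_params <- function(H, D) {
  list(W_u = matrix(rnorm(H * (H + D)), H, H + D),
       W_r = matrix(rnorm(H * (H + D)), H, H + D),
       W_hhat = matrix(rnorm(H * (H + D)), H, H + D))
}

random_lstm_params <- function(H, D) {
  m <- function(nc) matrix(rnorm(H * nc), H, nc)
  list(w_ix = m(D), w_fx = m(D), w_ox = m(D), w_cx = m(D),
       w_ih = m(H), w_fh = m(H), w_oh = m(H), w_ch = m(H))
}

# Linearly separable 3-class fixture: class c sits near 3 * e_c in a
# 6-dimensional feature space, far beyond the overlap of the noise.
separable_fset <- function(n_per_class = 40L, seed = 99L) {
  set.seed(seed)
  feats <- NULL; labs <- NULL
  for (cl in 0:2) {
    mu <- rep(0, 6); mu[cl + 1L] <- 3
    feats <- rbind(feats, matrix(rnorm(n_per_class * 6, 0, 0.3), ncol = 6) +
                     matrix(mu, n_per_class, 6, byrow = TRUE))
    labs <- c(labs, rep(cl, n_per_class))
  }
  ord <- sample(length(labs))
  feature_set(feats[ord, ], matrix(labs[ord], ncol = 1L), horizons = 1L,
              L = 2L, record_id = "sep", t_ref_s = seq_along(labs))
}

# Shared small synthetic corpus + ensemble cache, built once per session.
.fixture_env <- new.env(parent = emptyenv())

fixture_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    cfg <- generator_config("stress", duration_s = 300, seed = 10,
                            noise_sd = 0.05)
    .fixture_env$corpus <- generate_dataset(cfg, 2L, horizons = 1:10,
                                            L = 100L)
  }
  .fixture_env$corpus
}

fixture_config <- function(seed = 7L) {
  run_config(L = 100L, horizons = 1:10, k_folds = 3L, rng_seed = seed,
             training = list(hidden = 8L, window = 4L, epochs = 8L,
                             learning_rate = 0.05),
             nsga = list(pop_size = 24L, generations = 10L,
                         divisions_p = 3L))
}

fixture_cache <- function() {
  if (is.null(.fixture_env$cache)) {
    .fixture_env$cache <- build_ensemble_cache(fixture_corpus()$features,
                                               fixture_config())
  }
  .fixture_env$cache
}
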