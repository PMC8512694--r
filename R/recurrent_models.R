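## Recurrent multi-horizon classifiers built directly from the cell
## equations: Elman RNN with the power-sigmoid activation, GRU (update +
## reset gates, no bias terms), and LSTM (input/forget/output gates, no
## bias terms, corrected cell update C_t = f*C_{t-1} + i*C~_t). Gradients
## are derived analytically; no autodiff framework is used.

#' Power-sigmoid activation
#'
#' Piecewise activation used in the Elman RNN hidden layer:
#' `x^alpha` for `|x| >= 1`, and the scaled bipolar sigmoid
#' `(1+e^-beta)(1-e^-beta*x) / ((1-e^-beta)(1+e^-beta*x))` for `|x| < 1`.
#' With `alpha` odd (>= 3) and `beta > 2` the function is odd, strictly
#' increasing, and continuous everywhere (both branches equal +/-1 at
#' `x = +/-1`). The expansive polynomial branch accelerates convergence
#' away from the origin; the bounded branch is `c * tanh(beta*x/2)` with
#' `c = (1+e^-beta)/(1-e^-beta)`.
#'
#' @param x Numeric vector.
#' @param alpha Odd integer >= 3 (polynomial exponent).
#' @param beta Real > 2 (sigmoid steepness).
#' @return `sigma(x)`, same shape as `x`.
#' @export
power_sigmoid <- function(x, alpha = 3L, beta = 3) {
  check_psig(alpha, beta)
  out <- x
  big <- abs(x) >= 1
  out[big] <- x[big]^alpha
  cc <- (1 + exp(-beta)) / (1 - exp(-beta))
  out[!big] <- cc * tanh(beta * x[!big] / 2)
  out
}

check_psig <- function(alpha, beta) {
  if (alpha < 3 || alpha %% 2 != 1)
    stop("alpha must be an odd integer >= 3")
  if (beta <= 2) stop("beta must be > 2")
  invisible(TRUE)
}

power_sigmoid_prime <- function(x, alpha, beta) {
  out <- x
  big <- abs(x) >= 1
  out[big] <- alpha * x[big]^(alpha - 1)
  cc <- (1 + exp(-beta)) / (1 - exp(-beta))
  th <- tanh(beta * x[!big] / 2)
  out[!big] <- cc * (beta / 2) * (1 - th^2)
  out
}

# Bounded power-sigmoid branch extended to all x: smooth, odd, monotone,
# saturating at +/- (1+e^-beta)/(1-e^-beta). Used for the RNN output layer
# so logits stay finite for arbitrary pre-activations.
psig_bounded <- function(x, beta) {
  cc <- (1 + exp(-beta)) / (1 - exp(-beta))
  cc * tanh(beta * x / 2)
}

psig_bounded_prime <- function(x, beta) {
  cc <- (1 + exp(-beta)) / (1 - exp(-beta))
  cc * (beta / 2) * (1 - tanh(beta * x / 2)^2)
}

logistic <- function(x) 1 / (1 + exp(-x))

## ---- single-step cell equations (vector or row-matrix inputs) ----------

#' One Elman RNN step
#'
#' `h_t = sigma_h(W_ih x_t + W_h h_{t-1} + b_h)` followed by
#' `y_t = sigma_o(W_ho h_t + b_o)`, with `sigma_h` the full power-sigmoid
#' and `sigma_o` its bounded branch (see [power_sigmoid()]).
#'
#' @param x_t Input vector (length D) or n x D matrix.
#' @param h_prev Hidden state, length H or n x H.
#' @param p List with `W_ih` (H x D), `W_h` (H x H), `b_h` (H),
#'   `W_ho` (O x H), `b_o` (O), `alpha`, `beta`.
#' @return List with `h` and `y`.
#' @export
rnn_step <- function(x_t, h_prev, p) {
  x_t <- rbind(x_t); h_prev <- rbind(h_prev)
  if (ncol(x_t) != ncol(p$W_ih) || ncol(h_prev) != ncol(p$W_h))
    stop("shape mismatch in rnn_step")
  a <- x_t %*% t(p$W_ih) + h_prev %*% t(p$W_h) +
    matrix(p$b_h, nrow(x_t), length(p$b_h), byrow = TRUE)
  h <- power_sigmoid(a, p$alpha, p$beta)
  z <- h %*% t(p$W_ho) + matrix(p$b_o, nrow(h), length(p$b_o), byrow = TRUE)
  list(h = drop_row(h, x_t), y = drop_row(psig_bounded(z, p$beta), x_t))
}

#' One GRU step
#'
#' Update gate `u = sigma(W_u [h_{t-1}, x_t])`, reset gate
#' `r = sigma(W_r [h_{t-1}, x_t])`, candidate
#' `h~ = tanh(W_hhat [r * h_{t-1}, x_t])`, output
#' `h_t = (1-u) * h_{t-1} + u * h~` (Hadamard products). No bias terms.
#'
#' @param x_t Input vector or n x D matrix.
#' @param h_prev Hidden state, length H or n x H.
#' @param p List with `W_u`, `W_r`, `W_hhat`, each H x (H + D); the
#'   hidden block occupies the first H columns.
#' @return Hidden state `h_t`, same shape as `h_prev`.
#' @export
gru_step <- function(x_t, h_prev, p) {
  x_t <- rbind(x_t); h_prev <- rbind(h_prev)
  H <- ncol(h_prev)
  if (ncol(p$W_u) != H + ncol(x_t)) stop("shape mismatch in gru_step")
  cat1 <- cbind(h_prev, x_t)
  u <- logistic(cat1 %*% t(p$W_u))
  r <- logistic(cat1 %*% t(p$W_r))
  hh <- tanh(cbind(r * h_prev, x_t) %*% t(p$W_hhat))
  drop_row((1 - u) * h_prev + u * hh, x_t)
}

#' One LSTM step
#'
#' Gates `i = sigma(w_ix x + w_ih h_{t-1})`, `f = sigma(w_fx x + w_fh
#' h_{t-1})`, `o = sigma(w_ox x + w_oh h_{t-1})`, candidate
#' `C~ = tanh(w_cx x + w_ch h_{t-1})`; cell update
#' `C_t = f * C_{t-1} + i * C~` and output `h_t = o * tanh(C_t)`.
#' No bias terms.
#'
#' @param x_t Input vector or n x D matrix.
#' @param h_prev,c_prev Hidden and cell state, length H or n x H.
#' @param p List with `w_ix`, `w_fx`, `w_ox`, `w_cx` (H x D) and
#'   `w_ih`, `w_fh`, `w_oh`, `w_ch` (H x H).
#' @return List with `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, p) {
  x_t <- rbind(x_t); h_prev <- rbind(h_prev); c_prev <- rbind(c_prev)
  if (ncol(x_t) != ncol(p$w_ix) || ncol(h_prev) != ncol(p$w_ih))
    stop("shape mismatch in lstm_step")
  i <- logistic(x_t %*% t(p$w_ix) + h_prev %*% t(p$w_ih))
  f <- logistic(x_t %*% t(p$w_fx) + h_prev %*% t(p$w_fh))
  o <- logistic(x_t %*% t(p$w_ox) + h_prev %*% t(p$w_oh))
  ct <- tanh(x_t %*% t(p$w_cx) + h_prev %*% t(p$w_ch))
  cc <- f * c_prev + i * ct
  list(h = drop_row(o * tanh(cc), x_t), c = drop_row(cc, x_t))
}

drop_row <- function(m, ref) if (is.matrix(ref) && nrow(ref) > 1L) m else drop(m)

## ---- classifier construction -------------------------------------------

#' Construct an untrained multi-horizon recurrent classifier
#'
#' Wraps one recurrent cell (`"rnn"`, `"gru"` or `"lstm"`) in a
#' multi-horizon 3-class classifier: the cell consumes a sliding window of
#' `window` consecutive beat-pair feature vectors and the final hidden
#' state is read out as `n_horizons` independent 3-way softmax heads.
#' Weights are initialized uniformly in `+/- 1/sqrt(fan_in)` under `seed`.
#'
#' @param cell `"rnn"`, `"gru"` or `"lstm"`.
#' @param input_dim Feature dimension (398 for beat length L = 100).
#' @param hidden Hidden units H.
#' @param n_horizons Number of prediction heads (60 in the full protocol).
#' @param window Sliding-window length W in samples.
#' @param seed Integer seed for weight initialization.
#' @param alpha,beta Power-sigmoid parameters (RNN only).
#' @param n_classes Classes per head (fixed protocol value 3).
#' @return An object of class `horizon_classifier`.
#' @export
horizon_classifier <- function(cell = c("rnn", "gru", "lstm"), input_dim,
                               hidden = 16L, n_horizons = 60L, window = 8L,
                               seed = 1L, alpha = 3L, beta = 3,
                               n_classes = 3L) {
  cell <- match.arg(cell)
  check_psig(alpha, beta)
  D <- as.integer(input_dim); H <- as.integer(hidden)
  K <- as.integer(n_horizons); O <- K * as.integer(n_classes)
  old_seed <- sub_seed(seed, 101L)
  ru <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan),
                                     nr, nc)
  params <- switch(cell,
    rnn = list(W_ih = ru(H, D, D), W_h = ru(H, H, H), b_h = rep(0, H),
               W_ho = ru(O, H, H), b_o = rep(0, O),
               alpha = as.integer(alpha), beta = beta),
    gru = list(W_u = ru(H, H + D, H + D), W_r = ru(H, H + D, H + D),
               W_hhat = ru(H, H + D, H + D),
               W_out = ru(O, H, H), b_out = rep(0, O)),
    lstm = list(w_ix = ru(H, D, D), w_fx = ru(H, D, D), w_ox = ru(H, D, D),
                w_cx = ru(H, D, D), w_ih = ru(H, H, H), w_fh = ru(H, H, H),
                w_oh = ru(H, H, H), w_ch = ru(H, H, H),
                W_out = ru(O, H, H), b_out = rep(0, O)))
  restore_seed(old_seed)
  structure(list(cell = cell, input_dim = D, hidden = H, n_horizons = K,
                 n_classes = as.integer(n_classes), window = as.integer(window),
                 seed = as.integer(seed), alpha = as.integer(alpha),
                 beta = beta, params = params,
                 scale = list(mu = rep(0, D), sd = rep(1, D)),
                 loss_trace = numeric(0), trained = FALSE),
            class = "horizon_classifier")
}

#' @export
print.horizon_classifier <- function(x, ...) {
  cat(sprintf("<horizon_classifier %s: D=%d H=%d heads=%d window=%d %s>\n",
              toupper(x$cell), x$input_dim, x$hidden, x$n_horizons, x$window,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Derive a distinct, reproducible 32-bit seed from a base seed and a tag,
# set it, and return the previous RNG state for restoration.
sub_seed <- function(seed, tag) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((as.integer(seed) * 1009L + as.integer(tag)) %% 2147483587L)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## ---- sequence windows ---------------------------------------------------

# Sliding windows of W consecutive samples ending at each labeled sample.
# Rows must be in time order within each record; windows never cross a
# record boundary, and windows near a record start are left-padded by
# repeating the record's first sample. Returns a list of W matrices
# (step 1 = oldest), each n x D.
build_windows <- function(features, record_id, W) {
  n <- nrow(features)
  idx <- matrix(0L, n, W)
  runs <- rle(record_id)
  start <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  for (r in seq_along(runs$lengths)) {
    rows <- start[r]:(start[r] + runs$lengths[r] - 1L)
    for (w in seq_len(W)) {
      lag <- W - w
      idx[rows, w] <- pmax(rows - lag, rows[1L])
    }
  }
  lapply(seq_len(W), function(w) features[idx[, w], , drop = FALSE])
}

## ---- forward / backward -------------------------------------------------

# Forward pass over a window of steps. xs: list of W (n x D) matrices.
# Returns logits z (n x O), final hidden state, and caches for backprop.
hc_forward <- function(model, xs) {
  p <- model$params
  n <- nrow(xs[[1L]])
  H <- model$hidden
  W <- length(xs)
  h <- matrix(0, n, H)
  cache <- vector("list", W)
  if (model$cell == "rnn") {
    for (t in seq_len(W)) {
      a <- xs[[t]] %*% t(p$W_ih) + h %*% t(p$W_h) +
        matrix(p$b_h, n, H, byrow = TRUE)
      h_new <- power_sigmoid(a, p$alpha, p$beta)
      cache[[t]] <- list(a = a, h_prev = h)
      h <- h_new
    }
    zpre <- h %*% t(p$W_ho) + matrix(p$b_o, n, length(p$b_o), byrow = TRUE)
    z <- psig_bounded(zpre, p$beta)
    list(z = z, h = h, zpre = zpre, cache = cache)
  } else if (model$cell == "gru") {
    for (t in seq_len(W)) {
      cat1 <- cbind(h, xs[[t]])
      u <- logistic(cat1 %*% t(p$W_u))
      r <- logistic(cat1 %*% t(p$W_r))
      cat2 <- cbind(r * h, xs[[t]])
      hh <- tanh(cat2 %*% t(p$W_hhat))
      h_new <- (1 - u) * h + u * hh
      cache[[t]] <- list(cat1 = cat1, cat2 = cat2, u = u, r = r, hh = hh,
                         h_prev = h)
      h <- h_new
    }
    z <- h %*% t(p$W_out) + matrix(p$b_out, n, length(p$b_out), byrow = TRUE)
    list(z = z, h = h, cache = cache)
  } else {
    cc <- matrix(0, n, H)
    for (t in seq_len(W)) {
      i <- logistic(xs[[t]] %*% t(p$w_ix) + h %*% t(p$w_ih))
      f <- logistic(xs[[t]] %*% t(p$w_fx) + h %*% t(p$w_fh))
      o <- logistic(xs[[t]] %*% t(p$w_ox) + h %*% t(p$w_oh))
      ct <- tanh(xs[[t]] %*% t(p$w_cx) + h %*% t(p$w_ch))
      c_new <- f * cc + i * ct
      tc <- tanh(c_new)
      cache[[t]] <- list(i = i, f = f, o = o, ct = ct, c_prev = cc,
                         h_prev = h, tc = tc)
      h <- o * tc
      cc <- c_new
    }
    z <- h %*% t(p$W_out) + matrix(p$b_out, n, length(p$b_out), byrow = TRUE)
    list(z = z, h = h, cache = cache)
  }
}

# Per-head softmax of logits z (n x 3K). Returns n x 3 x K array.
head_softmax <- function(z, K) {
  n <- nrow(z)
  arr <- array(z, c(n, 3L, K))
  m <- pmax(arr[, 1L, , drop = FALSE], arr[, 2L, , drop = FALSE],
            arr[, 3L, , drop = FALSE])
  e <- exp(arr - m[, rep(1L, 3L), , drop = FALSE])
  s <- e[, 1L, , drop = FALSE] + e[, 2L, , drop = FALSE] +
    e[, 3L, , drop = FALSE]
  e / s[, rep(1L, 3L), , drop = FALSE]
}

# Mean cross-entropy over heads and samples, plus gradient wrt logits.
softmax_loss <- function(z, labels, K) {
  n <- nrow(z)
  probs <- head_softmax(z, K)
  onehot <- array(0, c(n, 3L, K))
  flat <- cbind(rep(seq_len(n), K), as.vector(labels) + 1L,
                rep(seq_len(K), each = n))
  onehot[flat] <- 1
  p_true <- probs[flat]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  dz <- matrix(aperm(probs - onehot, c(1L, 2L, 3L)), n, 3L * K) / (n * K)
  list(loss = loss, dz = dz, probs = probs)
}

# Backward pass; returns gradient list matching model$params layout.
hc_backward <- function(model, xs, fwd, dz) {
  p <- model$params
  W <- length(xs)
  H <- model$hidden
  if (model$cell == "rnn") {
    dzpre <- dz * psig_bounded_prime(fwd$zpre, p$beta)
    g <- list(W_ih = 0 * p$W_ih, W_h = 0 * p$W_h, b_h = 0 * p$b_h,
              W_ho = t(dzpre) %*% fwd$h, b_o = colSums(dzpre))
    dh <- dzpre %*% p$W_ho
    for (t in rev(seq_len(W))) {
      cc <- fwd$cache[[t]]
      da <- dh * power_sigmoid_prime(cc$a, p$alpha, p$beta)
      g$W_ih <- g$W_ih + t(da) %*% xs[[t]]
      g$W_h <- g$W_h + t(da) %*% cc$h_prev
      g$b_h <- g$b_h + colSums(da)
      dh <- da %*% p$W_h
    }
    g
  } else if (model$cell == "gru") {
    g <- list(W_u = 0 * p$W_u, W_r = 0 * p$W_r, W_hhat = 0 * p$W_hhat,
              W_out = t(dz) %*% fwd$h, b_out = colSums(dz))
    dh <- dz %*% p$W_out
    for (t in rev(seq_len(W))) {
      cc <- fwd$cache[[t]]
      du_pre <- dh * (cc$hh - cc$h_prev) * cc$u * (1 - cc$u)
      dhh_pre <- dh * cc$u * (1 - cc$hh^2)
      dcat2_h <- (dhh_pre %*% p$W_hhat)[, seq_len(H), drop = FALSE]
      dr_pre <- dcat2_h * cc$h_prev * cc$r * (1 - cc$r)
      g$W_u <- g$W_u + t(du_pre) %*% cc$cat1
      g$W_r <- g$W_r + t(dr_pre) %*% cc$cat1
      g$W_hhat <- g$W_hhat + t(dhh_pre) %*% cc$cat2
      dh <- dh * (1 - cc$u) + dcat2_h * cc$r +
        (du_pre %*% p$W_u)[, seq_len(H), drop = FALSE] +
        (dr_pre %*% p$W_r)[, seq_len(H), drop = FALSE]
    }
    g
  } else {
    g <- list(w_ix = 0 * p$w_ix, w_fx = 0 * p$w_fx, w_ox = 0 * p$w_ox,
              w_cx = 0 * p$w_cx, w_ih = 0 * p$w_ih, w_fh = 0 * p$w_fh,
              w_oh = 0 * p$w_oh, w_ch = 0 * p$w_ch,
              W_out = t(dz) %*% fwd$h, b_out = colSums(dz))
    dh <- dz %*% p$W_out
    dc <- matrix(0, nrow(dz), H)
    for (t in rev(seq_len(W))) {
      cc <- fwd$cache[[t]]
      do_pre <- dh * cc$tc * cc$o * (1 - cc$o)
      dc <- dc + dh * cc$o * (1 - cc$tc^2)
      df_pre <- dc * cc$c_prev * cc$f * (1 - cc$f)
      di_pre <- dc * cc$ct * cc$i * (1 - cc$i)
      dct_pre <- dc * cc$i * (1 - cc$ct^2)
      g$w_ix <- g$w_ix + t(di_pre) %*% xs[[t]]
      g$w_ih <- g$w_ih + t(di_pre) %*% cc$h_prev
      g$w_fx <- g$w_fx + t(df_pre) %*% xs[[t]]
      g$w_fh <- g$w_fh + t(df_pre) %*% cc$h_prev
      g$w_ox <- g$w_ox + t(do_pre) %*% xs[[t]]
      g$w_oh <- g$w_oh + t(do_pre) %*% cc$h_prev
      g$w_cx <- g$w_cx + t(dct_pre) %*% xs[[t]]
      g$w_ch <- g$w_ch + t(dct_pre) %*% cc$h_prev
      dh <- di_pre %*% p$w_ih + df_pre %*% p$w_fh + do_pre %*% p$w_oh +
        dct_pre %*% p$w_ch
      dc <- dc * cc$f
    }
    g
  }
}

numeric_params <- function(params)
  params[vapply(params, is.numeric, logical(1)) &
           !names(params) %in% c("alpha", "beta")]

## ---- training and prediction -------------------------------------------

#' Train a multi-horizon recurrent classifier
#'
#' Mini-batch gradient descent on the mean per-head cross-entropy, with
#' analytic backpropagation-through-time over the sliding window and
#' global-norm gradient clipping (the clip also guards the expansive
#' polynomial branch of the power-sigmoid). Features are standardized
#' per column on the training data; the scaling is stored in the model.
#' Fully deterministic given the model seed.
#'
#' @param model An untrained (or previously trained) [horizon_classifier()].
#' @param fset A [feature_set()] whose horizon count matches the model.
#' @param epochs Number of passes over the data (0 leaves the model as-is).
#' @param learning_rate Step size.
#' @param batch_size Mini-batch size.
#' @param clip_norm Global gradient-norm ceiling.
#' @param windows Optional precomputed raw-feature windows (list of W
#'   matrices aligned with the rows of `fset`), used when the rows are a
#'   subset of a larger time-ordered corpus (e.g. a CV fold) so that each
#'   sample keeps its true predecessors.
#' @return The fitted model with `loss_trace` (one mean loss per epoch).
#' @export
hc_train <- function(model, fset, epochs = 30L, learning_rate = 1e-3,
                     batch_size = 32L, clip_norm = 1.0, windows = NULL) {
  stopifnot(inherits(model, "horizon_classifier"),
            inherits(fset, "feature_set"))
  if (length(fset$horizons) != model$n_horizons)
    stop("feature set horizon count does not match the model")
  n <- nrow(fset$features)
  if (n < 1L) stop("empty feature set")
  if (length(unique(as.vector(fset$labels))) < 2L)
    warning("feature set contains a single class; training proceeds")
  mu <- colMeans(fset$features)
  sdv <- apply(fset$features, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  model$scale <- list(mu = mu, sd = sdv)
  if (epochs == 0L) { model$trained <- TRUE; return(model) }
  std <- function(m) sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  xs_all <- if (is.null(windows)) {
    build_windows(std(fset$features), fset$record_id, model$window)
  } else {
    stopifnot(length(windows) == model$window,
              nrow(windows[[1L]]) == n)
    lapply(windows, std)
  }
  K <- model$n_horizons
  old_seed <- sub_seed(model$seed, 211L)
  on.exit(restore_seed(old_seed))
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + batch_size - 1L, n)]
      xs <- lapply(xs_all, function(m) m[rows, , drop = FALSE])
      fwd <- hc_forward(model, xs)
      sm <- softmax_loss(fwd$z, fset$labels[rows, , drop = FALSE], K)
      grads <- hc_backward(model, xs, fwd, sm$dz)
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      scale <- if (gn > clip_norm) clip_norm / gn else 1
      for (nm in names(grads))
        model$params[[nm]] <- model$params[[nm]] -
          learning_rate * scale * grads[[nm]]
      ep_loss <- ep_loss + sm$loss * length(rows)
    }
    trace[ep] <- ep_loss / n
  }
  model$loss_trace <- c(model$loss_trace, trace)
  model$trained <- TRUE
  model
}

#' Predict multi-horizon classes and scores
#'
#' Applies the trained classifier to rows of a feature set (or a raw
#' feature matrix in time order). Per head, class scores are the softmax
#' of the logits (summing to 1) and the predicted class is the argmax,
#' ties broken toward the lowest class id.
#'
#' @param model A trained [horizon_classifier()].
#' @param features A [feature_set()] or numeric matrix (n x D) of
#'   consecutive samples in time order.
#' @param record_id Record ids per row when `features` is a bare matrix
#'   (windows never cross record boundaries).
#' @param windows Optional precomputed raw-feature windows, as in
#'   [hc_train()].
#' @return List with `classes` (n x K integer matrix, values 0-2) and
#'   `scores` (n x 3 x K array).
#' @export
hc_predict <- function(model, features, record_id = NULL, windows = NULL) {
  stopifnot(inherits(model, "horizon_classifier"))
  if (!model$trained) stop("model is untrained; call hc_train() first")
  if (inherits(features, "feature_set")) {
    record_id <- features$record_id
    features <- features$features
  }
  features <- as.matrix(features)
  if (is.null(record_id)) record_id <- rep("rec", nrow(features))
  std <- function(m) sweep(sweep(m, 2L, model$scale$mu), 2L,
                           model$scale$sd, "/")
  xs <- if (is.null(windows)) {
    build_windows(std(features), record_id, model$window)
  } else {
    lapply(windows, std)
  }
  fwd <- hc_forward(model, xs)
  K <- model$n_horizons
  probs <- head_softmax(fwd$z, K)
  classes <- apply(probs, c(1L, 3L), which.max) - 1L
  classes <- matrix(as.integer(classes), nrow(features), K)
  list(classes = classes, scores = probs)
}

#' Grid-search the power-sigmoid parameters
#'
#' Trains an RNN classifier for every `(alpha, beta)` pair on a seeded
#' 80/20 train/validation split and returns the pair maximizing overall
#' validation accuracy, together with the score table.
#'
#' @param fset A [feature_set()].
#' @param alphas,betas Candidate grids (defaults 3/5/7 and 3/4/5).
#' @param hidden,window,epochs,learning_rate,batch_size Training settings.
#' @param seed Seed controlling the split and weight init.
#' @return List with `alpha`, `beta`, and the `grid` of validation scores.
#' @export
tune_power_sigmoid <- function(fset, alphas = c(3L, 5L, 7L),
                               betas = c(3, 4, 5), hidden = 8L, window = 4L,
                               epochs = 10L, learning_rate = 0.05,
                               batch_size = 32L, seed = 1L) {
  n <- nrow(fset$features)
  old_seed <- sub_seed(seed, 307L)
  val <- sort(sample.int(n, max(1L, round(0.2 * n))))
  restore_seed(old_seed)
  tr <- setdiff(seq_len(n), val)
  grid <- expand.grid(alpha = alphas, beta = betas)
  grid$oa <- NA_real_
  for (g in seq_len(nrow(grid))) {
    m <- horizon_classifier("rnn", ncol(fset$features), hidden = hidden,
                            n_horizons = length(fset$horizons),
                            window = window, seed = seed,
                            alpha = grid$alpha[g], beta = grid$beta[g])
    m <- hc_train(m, subset_fset(fset, tr), epochs = epochs,
                  learning_rate = learning_rate, batch_size = batch_size)
    pr <- hc_predict(m, subset_fset(fset, val))
    grid$oa[g] <- overall_accuracy(as.vector(fset$labels[val, , drop = FALSE]),
                                   as.vector(pr$classes))
  }
  best <- which.max(grid$oa)
  list(alpha = grid$alpha[best], beta = grid$beta[best], grid = grid)
}

#' Serialize / restore a classifier as JSON
#'
#' Stores the cell kind, configuration, feature scaling, flattened weight
#' matrices with their shapes, and the loss trace; `read_model()` restores
#' an equivalent [horizon_classifier()].
#'
#' @param model A [horizon_classifier()].
#' @param path Output (input) JSON path.
#' @return `path` invisibly (writer); the restored model (reader).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "horizon_classifier"))
  num <- numeric_params(model$params)
  payload <- list(
    cell = model$cell, input_dim = model$input_dim, hidden = model$hidden,
    n_horizons = model$n_horizons, n_classes = model$n_classes,
    window = model$window, seed = model$seed, alpha = model$alpha,
    beta = model$beta, trained = model$trained,
    loss_trace = model$loss_trace,
    scale = model$scale,
    params = lapply(num, function(m) {
      if (is.matrix(m)) list(dim = dim(m), data = as.vector(m))
      else list(dim = length(m), data = as.vector(m))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- horizon_classifier(p$cell, p$input_dim, hidden = p$hidden,
                              n_horizons = p$n_horizons, window = p$window,
                              seed = p$seed, alpha = p$alpha, beta = p$beta,
                              n_classes = p$n_classes)
  for (nm in names(p$params)) {
    d <- p$params[[nm]]$dim
    v <- p$params[[nm]]$data
    model$params[[nm]] <- if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
  }
  model$scale <- list(mu = p$scale$mu, sd = p$scale$sd)
  model$loss_trace <- if (is.null(p$loss_trace)) numeric(0) else p$loss_trace
  model$trained <- isTRUE(p$trained)
  model
}

# Row subset of a feature_set.
subset_fset <- function(fset, rows) {
  feature_set(fset$features[rows, , drop = FALSE],
              fset$labels[rows, , drop = FALSE],
              fset$horizons, fset$L,
              record_id = fset$record_id[rows],
              t_ref_s = fset$t_ref_s[rows], seed = fset$seed)
}
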