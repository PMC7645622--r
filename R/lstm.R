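# LSTM cell, written out explicitly (the fusion classifier's recurrent
# core is authored here, not delegated): gates are sigmoids of affine maps
# of [h_{t-1}, x_t], the candidate cell is a tanh, the cell state mixes
# forget and input gates, and the hidden state is the output gate times
# tanh of the cell state.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' Weights are Gaussian with scale 1/sqrt(input_dim + hidden_dim); biases
#' start at zero except the forget-gate bias at 1 (the usual
#' remember-by-default initialization).
#'
#' @param input_dim length of each timestep input
#' @param hidden_dim hidden/cell state length
#' @param seed RNG seed
#' @return an `lstm_params` list of weight matrices
#'   `W_f, W_i, W_c, W_o` (hidden_dim x (hidden_dim + input_dim)) and bias
#'   vectors `b_f, b_i, b_c, b_o`
#' @export
lstm_params_init <- function(input_dim, hidden_dim, seed = 1) {
  d <- hidden_dim + input_dim
  sc <- 1 / sqrt(d)
  with_seed(seed, {
    p <- list(
      W_f = matrix(rnorm(hidden_dim * d, sd = sc), hidden_dim, d),
      W_i = matrix(rnorm(hidden_dim * d, sd = sc), hidden_dim, d),
      W_c = matrix(rnorm(hidden_dim * d, sd = sc), hidden_dim, d),
      W_o = matrix(rnorm(hidden_dim * d, sd = sc), hidden_dim, d),
      b_f = rep(1, hidden_dim),
      b_i = rep(0, hidden_dim),
      b_c = rep(0, hidden_dim),
      b_o = rep(0, hidden_dim)
    )
    structure(c(p, list(input_dim = input_dim, hidden_dim = hidden_dim)),
              class = "lstm_params")
  })
}

#' One LSTM step
#'
#' Computes, with z = [h_{t-1}, x_t]:
#' \deqn{f_t = \sigma(W_f z + b_f), \quad i_t = \sigma(W_i z + b_i)}
#' \deqn{c'_t = \tanh(W_c z + b_c), \quad o_t = \sigma(W_o z + b_o)}
#' \deqn{C_t = f_t \odot C_{t-1} + i_t \odot c'_t, \quad
#'       h_t = o_t \odot \tanh(C_t)}
#'
#' @param params an `lstm_params`
#' @param state list with `h` and `C` vectors of length hidden_dim
#' @param x_t input vector of length input_dim
#' @return updated state list with `h` and `C`
#' @export
lstm_step <- function(params, state, x_t) {
  if (length(x_t) != params$input_dim ||
      length(state$h) != params$hidden_dim ||
      length(state$C) != params$hidden_dim) {
    vox_abort("contract", "lstm_step input/state dimensions mismatch")
  }
  z <- c(state$h, x_t)
  f <- sigmoid(as.numeric(params$W_f %*% z) + params$b_f)
  i <- sigmoid(as.numeric(params$W_i %*% z) + params$b_i)
  cc <- tanh(as.numeric(params$W_c %*% z) + params$b_c)
  o <- sigmoid(as.numeric(params$W_o %*% z) + params$b_o)
  C <- f * state$C + i * cc
  list(h = o * tanh(C), C = C)
}

#' Run an LSTM over a 4-timestep pair sequence
#'
#' Folds [lstm_step()] over the rows of the sequence from a zero initial
#' state and returns the hidden state after the final (4th) timestep.
#'
#' @param params an `lstm_params`
#' @param steps a 4 x input_dim matrix (see [build_pair_sequence()])
#' @return hidden vector of length hidden_dim
#' @export
run_lstm <- function(params, steps) {
  if (!is.matrix(steps) || nrow(steps) != 4) {
    vox_abort("validation", "pair sequence must have exactly 4 timesteps")
  }
  state <- list(h = rep(0, params$hidden_dim),
                C = rep(0, params$hidden_dim))
  for (t in seq_len(nrow(steps))) {
    state <- lstm_step(params, state, steps[t, ])
  }
  state$h
}

# ---- batched forward/backward used by training --------------------------
# X: list of T matrices, each input_dim x n (columns are samples).

lstm_forward_batch <- function(params, X) {
  n <- ncol(X[[1]])
  hd <- params$hidden_dim
  h <- matrix(0, hd, n)
  C <- matrix(0, hd, n)
  cache <- vector("list", length(X))
  for (t in seq_along(X)) {
    z <- rbind(h, X[[t]])
    f <- sigmoid(params$W_f %*% z + params$b_f)
    i <- sigmoid(params$W_i %*% z + params$b_i)
    cc <- tanh(params$W_c %*% z + params$b_c)
    o <- sigmoid(params$W_o %*% z + params$b_o)
    C_prev <- C
    C <- f * C_prev + i * cc
    tC <- tanh(C)
    h <- o * tC
    cache[[t]] <- list(z = z, f = f, i = i, cc = cc, o = o,
                       C_prev = C_prev, C = C, tC = tC)
  }
  list(h = h, cache = cache)
}

# dh_last: hidden_dim x n gradient on the final hidden state.
lstm_backward_batch <- function(params, cache, dh_last) {
  hd <- params$hidden_dim
  grads <- list(W_f = 0 * params$W_f, W_i = 0 * params$W_i,
                W_c = 0 * params$W_c, W_o = 0 * params$W_o,
                b_f = 0 * params$b_f, b_i = 0 * params$b_i,
                b_c = 0 * params$b_c, b_o = 0 * params$b_o)
  dh <- dh_last
  dC <- matrix(0, nrow(dh_last), ncol(dh_last))
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    do <- dh * cc$tC
    dC <- dC + dh * cc$o * (1 - cc$tC^2)
    df <- dC * cc$C_prev
    di <- dC * cc$cc
    dcc <- dC * cc$i
    dC_prev <- dC * cc$f
    d_f <- df * cc$f * (1 - cc$f)
    d_i <- di * cc$i * (1 - cc$i)
    d_c <- dcc * (1 - cc$cc^2)
    d_o <- do * cc$o * (1 - cc$o)
    zt <- t(cc$z)
    grads$W_f <- grads$W_f + d_f %*% zt
    grads$W_i <- grads$W_i + d_i %*% zt
    grads$W_c <- grads$W_c + d_c %*% zt
    grads$W_o <- grads$W_o + d_o %*% zt
    grads$b_f <- grads$b_f + rowSums(d_f)
    grads$b_i <- grads$b_i + rowSums(d_i)
    grads$b_c <- grads$b_c + rowSums(d_c)
    grads$b_o <- grads$b_o + rowSums(d_o)
    dz <- t(params$W_f) %*% d_f + t(params$W_i) %*% d_i +
      t(params$W_c) %*% d_c + t(params$W_o) %*% d_o
    dh <- dz[seq_len(hd), , drop = FALSE]
    dC <- dC_prev
  }
  grads
}

# ---- Adam optimizer over named lists of arrays --------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p))
}

adam_update <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
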