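# Single-hidden-layer autoencoder used to compress the AC and CT pair
# encodings to a common feature-axis length before fusion. Encoder and
# decoder are linear (the optimum then coincides with the principal
# subspace, which makes convergence behaviour easy to reason about and
# test); fitting is by Adam on mean squared reconstruction error.

#' Fit a single-hidden-layer autoencoder
#'
#' Minimizes mean squared reconstruction error of
#' `decode(encode(x)) = W_d (W_e x + b_e) + b_d` by minibatch Adam.
#' Deterministic given `seed`.
#'
#' @param X numeric matrix, one training vector per row
#' @param code_dim hidden-code length; a `code_dim >= ncol(X)` is allowed
#'   but pointless for compression, so it is flagged with a warning
#' @param epochs training epochs (default 200)
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param seed RNG seed for initialization and shuffling
#' @param identity_init if `TRUE` (only valid when `code_dim == ncol(X)`),
#'   start encoder and decoder near the identity map
#' @return an `autoencoder` list with `W_e`, `b_e`, `W_d`, `b_d`,
#'   `code_dim`, and a per-epoch `loss` vector
#' @export
fit_autoencoder <- function(X, code_dim, epochs = 200, lr = 1e-2,
                            batch_size = 32, seed = 1,
                            identity_init = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2) vox_abort("validation", "autoencoder needs >= 2 vectors")
  code_dim <- stopifnot_scalar_int(code_dim, "code_dim")
  if (code_dim >= d) {
    vox_warn("config",
             sprintf("code_dim %d >= input_dim %d: no compression",
                     code_dim, d))
  }
  if (identity_init && code_dim != d) {
    vox_abort("config", "identity_init requires code_dim == input_dim")
  }
  with_seed(seed, {
    sc <- 1 / sqrt(d)
    params <- if (identity_init) {
      list(W_e = diag(d) + matrix(rnorm(d * d, sd = 1e-3), d, d),
           b_e = rep(0, d),
           W_d = diag(d) + matrix(rnorm(d * d, sd = 1e-3), d, d),
           b_d = rep(0, d))
    } else {
      list(W_e = matrix(rnorm(code_dim * d, sd = sc), code_dim, d),
           b_e = rep(0, code_dim),
           W_d = matrix(rnorm(d * code_dim, sd = 1 / sqrt(code_dim)),
                        d, code_dim),
           b_d = rep(0, d))
    }
    opt <- adam_init(params, lr = lr)
    loss <- numeric(epochs)
    Xt <- t(X)                                    # d x n, columns samples
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (b in batches) {
        xb <- Xt[, b, drop = FALSE]
        code <- params$W_e %*% xb + params$b_e
        recon <- params$W_d %*% code + params$b_d
        err <- recon - xb                          # d x m
        m <- length(b)
        dr <- 2 * err / (m * d)
        grads <- list(
          W_e = t(params$W_d) %*% dr %*% t(xb),
          b_e = rowSums(t(params$W_d) %*% dr),
          W_d = dr %*% t(code),
          b_d = rowSums(dr)
        )
        upd <- adam_update(opt, params, grads)
        opt <- upd$opt
        params <- upd$params
      }
      recon_all <- params$W_d %*% (params$W_e %*% Xt + params$b_e) +
        params$b_d
      loss[ep] <- mean((recon_all - Xt)^2)
    }
    structure(c(params, list(code_dim = code_dim, input_dim = d,
                             loss = loss, seed = seed)),
              class = "autoencoder")
  })
}

#' Encode vectors with a fitted autoencoder
#'
#' @param ae an `autoencoder` from [fit_autoencoder()]
#' @param X numeric matrix (rows are vectors) or a single vector
#' @return matrix of codes, one row per input row
#' @export
ae_encode <- function(ae, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  t(ae$W_e %*% t(X) + ae$b_e)
}

#' Reconstruct vectors with a fitted autoencoder
#'
#' @inheritParams ae_encode
#' @return matrix of reconstructions, one row per input row
#' @export
ae_reconstruct <- function(ae, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  code <- ae$W_e %*% t(X) + ae$b_e
  t(ae$W_d %*% code + ae$b_d)
}
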