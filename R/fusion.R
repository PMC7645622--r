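# The multimodal fusion classifier.
#
# Architecture: the 4-timestep structural pair sequence runs through an
# LSTM whose final hidden state is concatenated with autoencoder codes of
# the paired AC and CT sequence encodings; a sigmoid output unit on the
# fused vector gives the interaction probability. The LSTM and output
# layer are trained jointly by minibatch Adam on binary cross-entropy; the
# autoencoders are fit beforehand on the training pairs' sequence features
# only and then frozen.

#' Fusion model configuration
#'
#' @param hidden_dim LSTM hidden/cell size (default 512)
#' @param ac_code_dim,ct_code_dim autoencoder code lengths for the AC and
#'   CT segments (default 512 each, matching `hidden_dim` so all fused
#'   segments share one feature-axis length)
#' @param modalities feature segments to fuse; `"structural"` is always
#'   required, `"ac"` and `"ct"` can be ablated
#' @param epochs,batch_size,learning_rate Adam training schedule for the
#'   LSTM + output layer
#' @param ae_epochs,ae_learning_rate Adam schedule for the autoencoders
#' @param weight_decay decoupled L2 weight decay applied to the LSTM and
#'   output weight matrices each update (biases excluded); the main
#'   regularizer against memorizing small training sets
#' @param threshold decision threshold; label 1 requires probability
#'   strictly greater than it
#' @param seed run seed; all initialization and shuffling derives from it
#' @return a `fusion_config` list
#' @export
fusion_config <- function(hidden_dim = 512, ac_code_dim = 512,
                          ct_code_dim = 512,
                          modalities = c("structural", "ac", "ct"),
                          epochs = 30, batch_size = 32,
                          learning_rate = 1e-3,
                          ae_epochs = 100, ae_learning_rate = 1e-2,
                          weight_decay = 1e-2,
                          threshold = 0.5, seed = 1) {
  modalities <- match.arg(modalities, c("structural", "ac", "ct"),
                          several.ok = TRUE)
  if (!"structural" %in% modalities) {
    vox_abort("config", "the structural modality cannot be ablated")
  }
  structure(list(hidden_dim = hidden_dim, ac_code_dim = ac_code_dim,
                 ct_code_dim = ct_code_dim, modalities = modalities,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, ae_epochs = ae_epochs,
                 ae_learning_rate = ae_learning_rate,
                 weight_decay = weight_decay,
                 threshold = threshold, seed = seed),
            class = "fusion_config")
}

# named list id -> 4 x d matrix from a structural feature table
structural_lookup <- function(struct) {
  mats <- lapply(struct$vec, structural_to_matrix)
  names(mats) <- struct$id
  mats
}

require_ids <- function(ids, have, what) {
  missing <- setdiff(ids, have)
  if (length(missing) > 0) {
    vox_abort("validation",
              sprintf("missing %s features for protein(s): %s", what,
                      paste(head(missing, 5), collapse = ", ")))
  }
}

# X: list of 4 matrices (input_dim x n), columns are pairs
pair_step_inputs <- function(pairs, struct) {
  mats <- structural_lookup(struct)
  require_ids(unique(c(pairs$id_a, pairs$id_b)), names(mats), "structural")
  lapply(1:4, function(t) {
    a <- vapply(pairs$id_a, function(id) mats[[id]][t, ],
                numeric(ncol(mats[[1]])))
    b <- vapply(pairs$id_b, function(id) mats[[id]][t, ],
                numeric(ncol(mats[[1]])))
    unname(rbind(a, b))
  })
}

# n x (2 d) matrix of concatenated A-then-B sequence features.
# CT count vectors are first normalized to window frequencies per protein:
# raw triad counts scale with sequence length and z-scoring their sparse
# columns amplifies rare-triad noise, drowning the compositional signal.
pair_seq_matrix <- function(pairs, feats, what) {
  m <- feature_matrix(feats)
  if (what == "CT") {
    tot <- rowSums(m)
    tot[tot == 0] <- 1
    m <- m / tot
  }
  require_ids(unique(c(pairs$id_a, pairs$id_b)), rownames(m), what)
  cbind(m[pairs$id_a, , drop = FALSE], m[pairs$id_b, , drop = FALSE])
}

# global_sd: centre per column but scale by one pooled sd, preserving the
# relative magnitude of columns (used for the frequency-scale CT block)
fit_scaler <- function(m, by_row = FALSE, global_sd = FALSE) {
  if (by_row) m <- t(m)
  mu <- colMeans(m)
  sig <- if (global_sd) {
    s <- sd(sweep(m, 2, mu))
    rep(if (!is.finite(s) || s == 0) 1 else s, ncol(m))
  } else {
    apply(m, 2, sd)
  }
  sig[!is.finite(sig) | sig == 0] <- 1
  list(mean = mu, sd = sig)
}

apply_scaler_cols <- function(m, sc) {
  sweep(sweep(m, 2, sc$mean), 2, sc$sd, "/")
}

apply_scaler_rows <- function(m, sc) {
  (m - sc$mean) / sc$sd
}

#' Train the multimodal fusion classifier
#'
#' Fits the autoencoders on the training pairs' AC/CT features, then
#' trains the LSTM and sigmoid output layer jointly by minibatch Adam on
#' binary cross-entropy. All feature segments are standardized with
#' statistics computed on the training pairs and stored in the model.
#'
#' @param pairs tibble with columns `id_a`, `id_b`, `label` (both classes
#'   must be present)
#' @param struct structural feature table (tag `"structural"`,
#'   see [embed_proteins()])
#' @param ac,ct AC/CT feature tables; may be `NULL` when the corresponding
#'   modality is ablated in `config`
#' @param config a [fusion_config()]
#' @return a `ppi_fusion` model; its training log is available via
#'   [tidy.ppi_fusion()]
#' @export
ppi_train <- function(pairs, struct, ac = NULL, ct = NULL,
                      config = fusion_config()) {
  y <- as.integer(pairs$label)
  if (length(unique(y)) < 2) {
    vox_abort("validation", "training pairs must contain both classes")
  }
  n <- nrow(pairs)
  use_ac <- "ac" %in% config$modalities
  use_ct <- "ct" %in% config$modalities

  X <- pair_step_inputs(pairs, struct)
  struct_scalers <- lapply(X, function(m) fit_scaler(m, by_row = TRUE))
  X <- Map(apply_scaler_rows, X, struct_scalers)
  input_dim <- nrow(X[[1]])

  ae_ac <- ae_ct <- NULL
  ac_scaler <- ct_scaler <- NULL
  Z_ac <- Z_ct <- NULL
  if (use_ac) {
    M <- pair_seq_matrix(pairs, ac, "AC")
    ac_scaler <- fit_scaler(M)
    M <- apply_scaler_cols(M, ac_scaler)
    ae_ac <- fit_autoencoder(M, config$ac_code_dim,
                             epochs = config$ae_epochs,
                             lr = config$ae_learning_rate,
                             batch_size = config$batch_size,
                             seed = child_seed(config$seed, 1))
    Z_ac <- ae_encode(ae_ac, M)
  }
  if (use_ct) {
    M <- pair_seq_matrix(pairs, ct, "CT")
    ct_scaler <- fit_scaler(M, global_sd = TRUE)
    M <- apply_scaler_cols(M, ct_scaler)
    ae_ct <- fit_autoencoder(M, config$ct_code_dim,
                             epochs = config$ae_epochs,
                             lr = config$ae_learning_rate,
                             batch_size = config$batch_size,
                             seed = child_seed(config$seed, 2))
    Z_ct <- ae_encode(ae_ct, M)
  }

  hd <- config$hidden_dim
  fused_dim <- hd + (if (use_ac) config$ac_code_dim else 0) +
    (if (use_ct) config$ct_code_dim else 0)
  lstm <- lstm_params_init(input_dim, hd, seed = child_seed(config$seed, 3))
  out <- with_seed(child_seed(config$seed, 4), {
    list(W_out = matrix(rnorm(fused_dim, sd = 1 / sqrt(fused_dim)),
                        nrow = 1),
         b_out = 0)
  })

  lstm_nms <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o")
  all_params <- c(lstm[lstm_nms], out)
  opt <- adam_init(all_params, lr = config$learning_rate)
  log <- tibble(epoch = integer(), loss = numeric(),
                train_accuracy = numeric())

  with_seed(child_seed(config$seed, 5), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        Xb <- lapply(X, function(m) m[, b, drop = FALSE])
        fw <- lstm_forward_batch(lstm, Xb)
        fused <- fw$h
        if (use_ac) fused <- rbind(fused, t(Z_ac[b, , drop = FALSE]))
        if (use_ct) fused <- rbind(fused, t(Z_ct[b, , drop = FALSE]))
        logits <- as.numeric(all_params$W_out %*% fused) + all_params$b_out
        prob <- sigmoid(logits)
        m_b <- length(b)
        dlogit <- matrix((prob - y[b]) / m_b, nrow = 1)
        grads_out <- list(W_out = dlogit %*% t(fused),
                          b_out = sum(dlogit))
        dh <- t(all_params$W_out[, seq_len(hd), drop = FALSE]) %*% dlogit
        grads_lstm <- lstm_backward_batch(lstm, fw$cache, dh)
        upd <- adam_update(opt, all_params, c(grads_lstm, grads_out))
        opt <- upd$opt
        all_params <- upd$params
        decay <- 1 - config$learning_rate * config$weight_decay
        for (nm in c("W_f", "W_i", "W_c", "W_o", "W_out")) {
          all_params[[nm]] <- all_params[[nm]] * decay
        }
        lstm[lstm_nms] <- all_params[lstm_nms]
      }
      fw <- lstm_forward_batch(lstm, X)
      fused <- fw$h
      if (use_ac) fused <- rbind(fused, t(Z_ac))
      if (use_ct) fused <- rbind(fused, t(Z_ct))
      prob <- sigmoid(as.numeric(all_params$W_out %*% fused) +
                        all_params$b_out)
      eps <- 1e-12
      log <- dplyr::bind_rows(log, tibble(
        epoch = ep,
        loss = -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps)),
        train_accuracy = mean((prob > config$threshold) == (y == 1))
      ))
    }
  })

  structure(list(
    config = config, lstm = lstm,
    W_out = all_params$W_out, b_out = all_params$b_out,
    ae_ac = ae_ac, ae_ct = ae_ct,
    struct_scalers = struct_scalers,
    ac_scaler = ac_scaler, ct_scaler = ct_scaler,
    log = log,
    # leakage guard: the autoencoders and scalers saw exactly these pairs
    train_ids = sort(unique(c(pairs$id_a, pairs$id_b))),
    n_train_pairs = n
  ), class = "ppi_fusion")
}

#' Build fused feature vectors for protein pairs
#'
#' Runs the model's LSTM over each pair's structural sequence and
#' concatenates the final hidden state with the (frozen) autoencoder codes
#' of the paired AC and CT features:
#' `fused = [h_last, encode_ac(AC_a, AC_b), encode_ct(CT_a, CT_b)]`.
#'
#' @param model a trained `ppi_fusion`
#' @param pairs tibble with `id_a`, `id_b`
#' @param struct,ac,ct feature tables covering all referenced proteins
#' @return numeric matrix, one fused row per pair
#' @export
fuse_pair_features <- function(model, pairs, struct, ac = NULL, ct = NULL) {
  X <- pair_step_inputs(pairs, struct)
  X <- Map(apply_scaler_rows, X, model$struct_scalers)
  fused <- lstm_forward_batch(model$lstm, X)$h
  if (!is.null(model$ae_ac)) {
    if (is.null(ac)) vox_abort("validation", "model requires AC features")
    M <- apply_scaler_cols(pair_seq_matrix(pairs, ac, "AC"),
                           model$ac_scaler)
    fused <- rbind(fused, t(ae_encode(model$ae_ac, M)))
  }
  if (!is.null(model$ae_ct)) {
    if (is.null(ct)) vox_abort("validation", "model requires CT features")
    M <- apply_scaler_cols(pair_seq_matrix(pairs, ct, "CT"),
                           model$ct_scaler)
    fused <- rbind(fused, t(ae_encode(model$ae_ct, M)))
  }
  t(fused)
}

#' Predict interaction probabilities for protein pairs
#'
#' @param object a trained `ppi_fusion`
#' @param pairs tibble with `id_a`, `id_b` (a `label` column, if present,
#'   is carried through)
#' @param struct,ac,ct feature tables covering all referenced proteins
#' @param ... unused
#' @return tibble with `id_a`, `id_b`, `prob` and `pred` (1 iff `prob`
#'   strictly exceeds the configured threshold)
#' @export
predict.ppi_fusion <- function(object, pairs, struct, ac = NULL, ct = NULL,
                               ...) {
  fused <- fuse_pair_features(object, pairs, struct, ac, ct)
  prob <- sigmoid(as.numeric(object$W_out %*% t(fused)) + object$b_out)
  out <- tibble(id_a = pairs$id_a, id_b = pairs$id_b, prob = prob,
                pred = as.integer(prob > object$config$threshold))
  if ("label" %in% names(pairs)) out$label <- as.integer(pairs$label)
  out
}

#' @export
print.ppi_fusion <- function(x, ...) {
  cat(sprintf(
    "<ppi_fusion: hidden=%d, modalities=%s, %d epochs, final loss %.4f>\n",
    x$config$hidden_dim, paste(x$config$modalities, collapse = "+"),
    nrow(x$log), tail(x$log$loss, 1)))
  invisible(x)
}

#' Training log of a fusion model
#'
#' @param x a `ppi_fusion`
#' @param ... unused
#' @return tibble with one row per epoch: `epoch`, `loss`,
#'   `train_accuracy`
#' @method tidy ppi_fusion
#' @export
tidy.ppi_fusion <- function(x, ...) x$log

#' One-row summary of a fusion model
#'
#' @param x a `ppi_fusion`
#' @param ... unused
#' @return one-row tibble: seed, epochs, final loss and train accuracy,
#'   fused dimension, number of training pairs
#' @method glance ppi_fusion
#' @export
glance.ppi_fusion <- function(x, ...) {
  tibble(
    seed = x$config$seed,
    epochs = nrow(x$log),
    final_loss = tail(x$log$loss, 1),
    final_train_accuracy = tail(x$log$train_accuracy, 1),
    fused_dim = ncol(x$W_out),
    n_train_pairs = x$n_train_pairs
  )
}

#' Plot a fusion model's training curves
#'
#' @param object a `ppi_fusion`
#' @param ... unused
#' @return a ggplot of loss and training accuracy by epoch
#' @method autoplot ppi_fusion
#' @export
autoplot.ppi_fusion <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
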