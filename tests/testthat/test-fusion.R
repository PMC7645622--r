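# LSTM cell, autoencoder, and the fusion classifier's training loop.

test_that("lstm_step with zero parameters gives half-open gates", {
  hd <- 4; id <- 6
  p <- lstm_params_init(id, hd, seed = 1)
  for (nm in c("W_f", "W_i", "W_c", "W_o")) p[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_c", "b_o")) p[[nm]][] <- 0
  st <- lstm_step(p, list(h = rep(0, hd), C = rep(0, hd)), rep(1, id))
  # sigma(0) = 0.5 and tanh(0) = 0, so the cell and hidden stay zero
  expect_equal(st$C, rep(0, hd))
  expect_equal(st$h, rep(0, hd))
})

test_that("gate activations stay in range and bound the hidden state", {
  for (s in 1:10) {
    p <- lstm_params_init(8, 5, seed = s)
    x <- withr::with_seed(s, rnorm(8, sd = 3))
    st <- list(h = withr::with_seed(s + 1, runif(5, -1, 1)),
               C = withr::with_seed(s + 2, rnorm(5)))
    out <- lstm_step(p, st, x)
    expect_true(all(is.finite(out$C)))
    expect_true(all(abs(out$h) < 1))   # |o| < 1 and |tanh(C)| < 1
  }
})

test_that("lstm_step matches the scalar transliteration oracle", {
  for (s in 1:50) {
    hd <- withr::with_seed(s, sample(2:6, 1))
    id <- withr::with_seed(s + 1, sample(3:8, 1))
    p <- lstm_params_init(id, hd, seed = s)
    h0 <- withr::with_seed(s + 2, rnorm(hd))
    C0 <- withr::with_seed(s + 3, rnorm(hd))
    x <- withr::with_seed(s + 4, rnorm(id))
    got <- lstm_step(p, list(h = h0, C = C0), x)
    want <- oracle_lstm_step(p, h0, C0, x)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$C, want$C, tolerance = 1e-10)
  }
})

test_that("run_lstm folds four steps from a zero state", {
  p <- lstm_params_init(6, 4, seed = 2)
  steps <- matrix(withr::with_seed(3, rnorm(24)), 4, 6)
  manual <- list(h = rep(0, 4), C = rep(0, 4))
  for (t in 1:4) manual <- lstm_step(p, manual, steps[t, ])
  expect_equal(run_lstm(p, steps), manual$h)

  # zero weights give a zero representation
  p0 <- p
  for (nm in c("W_f", "W_i", "W_c", "W_o")) p0[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_c", "b_o")) p0[[nm]][] <- 0
  expect_equal(run_lstm(p0, steps), rep(0, 4))

  # timestep order matters for generic parameters
  expect_false(isTRUE(all.equal(run_lstm(p, steps),
                                run_lstm(p, steps[4:1, ]))))
  expect_error(run_lstm(p, steps[1:3, ]),
               class = "voxppi_error_validation")
})

test_that("batched forward agrees with run_lstm and backward with
           numerical gradients", {
  hd <- 3; id <- 4; n <- 5
  p <- lstm_params_init(id, hd, seed = 9)
  X <- withr::with_seed(10, lapply(1:4, function(t) matrix(rnorm(id * n),
                                                           id, n)))
  fw <- voxppi:::lstm_forward_batch(p, X)
  for (j in 1:n) {
    steps <- t(vapply(X, function(m) m[, j], numeric(id)))
    expect_equal(fw$h[, j], run_lstm(p, steps), tolerance = 1e-12)
  }

  # scalar loss L = sum(h_last); analytic vs central-difference gradients
  dh <- matrix(1, hd, n)
  gr <- voxppi:::lstm_backward_batch(p, fw$cache, dh)
  loss_of <- function(p2) sum(voxppi:::lstm_forward_batch(p2, X)$h)
  eps <- 1e-6
  for (nm in c("W_f", "W_c", "b_o")) {
    idx <- if (is.matrix(p[[nm]])) c(2, 3) else 2
    p_plus <- p; p_minus <- p
    if (is.matrix(p[[nm]])) {
      p_plus[[nm]][idx[1], idx[2]] <- p[[nm]][idx[1], idx[2]] + eps
      p_minus[[nm]][idx[1], idx[2]] <- p[[nm]][idx[1], idx[2]] - eps
      analytic <- gr[[nm]][idx[1], idx[2]]
    } else {
      p_plus[[nm]][idx] <- p[[nm]][idx] + eps
      p_minus[[nm]][idx] <- p[[nm]][idx] - eps
      analytic <- gr[[nm]][idx]
    }
    numeric_grad <- (loss_of(p_plus) - loss_of(p_minus)) / (2 * eps)
    expect_equal(analytic, numeric_grad, tolerance = 1e-5)
  }
})

test_that("the autoencoder recovers a linear subspace", {
  d <- 10; k <- 3; n <- 200
  X <- withr::with_seed(5, {
    basis <- matrix(rnorm(d * k), d, k)
    codes <- matrix(rnorm(n * k), n, k)
    codes %*% t(basis)
  })
  ae <- fit_autoencoder(X, code_dim = k, epochs = 400, seed = 5)
  expect_lt(mean((ae_reconstruct(ae, X) - X)^2), 1e-3)
  expect_equal(dim(ae_encode(ae, X)), c(n, k))
})

test_that("the autoencoder is deterministic and flags useless widths", {
  X <- withr::with_seed(6, matrix(rnorm(50 * 8), 50, 8))
  a1 <- fit_autoencoder(X, 3, epochs = 20, seed = 7)
  a2 <- fit_autoencoder(X, 3, epochs = 20, seed = 7)
  expect_identical(a1$W_e, a2$W_e)
  expect_identical(a1$loss, a2$loss)
  expect_warning(fit_autoencoder(X, 8, epochs = 2, seed = 1),
                 class = "voxppi_warning_config")
  expect_error(fit_autoencoder(X[1, , drop = FALSE], 2),
               class = "voxppi_error_validation")
})

test_that("a full-width identity-initialized autoencoder reconstructs
           better than a bottleneck", {
  X <- withr::with_seed(8, matrix(rnorm(60 * 6), 60, 6))
  full <- suppressWarnings(
    fit_autoencoder(X, 6, epochs = 50, seed = 2, identity_init = TRUE))
  narrow <- fit_autoencoder(X, 2, epochs = 50, seed = 2)
  expect_lt(tail(full$loss, 1), tail(narrow$loss, 1))
})

# -- a tiny planted pair problem reused by the classifier tests ----------

tiny_pair_problem <- function(seed = 1, n_prot = 16, n_pairs = 60) {
  withr::with_seed(seed, {
    d <- 6
    u <- rnorm(n_prot)
    ids <- sprintf("q%02d", seq_len(n_prot))
    # structural features: 4 channels whose mean tracks u, plus noise
    struct <- feature_table(ids, lapply(u, function(ui) {
      as.numeric(t(matrix(ui + rnorm(4 * d, sd = 0.2), 4, d)))
    }), "structural")
    ac <- feature_table(ids, lapply(u, function(ui) {
      ui + rnorm(10, sd = 0.2)
    }), "AC")
    ct <- feature_table(ids, lapply(u, function(ui) {
      abs(ui + rnorm(12, sd = 0.2))
    }), "CT")
    comb <- t(combn(n_prot, 2))
    pick <- sample(nrow(comb), n_pairs)
    s <- u[comb[pick, 1]] + u[comb[pick, 2]]
    pairs <- tibble::tibble(id_a = ids[comb[pick, 1]],
                            id_b = ids[comb[pick, 2]],
                            label = as.integer(s > stats::median(s)))
    list(pairs = pairs, struct = struct, ac = ac, ct = ct)
  })
}

small_config <- function(...) {
  fusion_config(hidden_dim = 4, ac_code_dim = 4, ct_code_dim = 4,
                epochs = 30, ae_epochs = 20, weight_decay = 0.1,
                seed = 5, ...)
}

test_that("training is deterministic given the seed", {
  pr <- tiny_pair_problem()
  m1 <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  m2 <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  expect_identical(m1$W_out, m2$W_out)
  expect_identical(m1$lstm$W_f, m2$lstm$W_f)
  p1 <- predict(m1, pr$pairs, pr$struct, pr$ac, pr$ct)
  p2 <- predict(m2, pr$pairs, pr$struct, pr$ac, pr$ct)
  expect_identical(p1$prob, p2$prob)
})

test_that("training accuracy improves on separable planted data", {
  pr <- tiny_pair_problem(seed = 3)
  m <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  log <- tidy(m)
  expect_gt(tail(log$train_accuracy, 1), log$train_accuracy[1])
  expect_gt(cor(log$epoch, log$train_accuracy, method = "spearman"), 0)
  expect_lt(tail(log$loss, 1), log$loss[1])
})

test_that("fused vectors concatenate hidden state and modality codes", {
  pr <- tiny_pair_problem()
  m <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  fused <- fuse_pair_features(m, pr$pairs, pr$struct, pr$ac, pr$ct)
  expect_equal(ncol(fused), 12)        # 4 + 4 + 4
  # ablations drop the corresponding segment
  for (mod in list(c("structural"), c("structural", "ac"),
                   c("structural", "ct"))) {
    ma <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct,
                    small_config(modalities = mod))
    fa <- fuse_pair_features(ma, pr$pairs, pr$struct, pr$ac, pr$ct)
    expect_equal(ncol(fa), 4 * length(mod))
  }
})

test_that("the advertised default dimensions fuse to 1536", {
  pr <- tiny_pair_problem(n_prot = 8, n_pairs = 20)
  cfg <- fusion_config(epochs = 1, ae_epochs = 1, seed = 1)
  m <- suppressWarnings(ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, cfg))
  fused <- fuse_pair_features(m, pr$pairs[1:2, ], pr$struct, pr$ac, pr$ct)
  expect_equal(ncol(fused), 1536)      # 512 + 512 + 512
})

test_that("prediction follows the strict 0.5 threshold convention", {
  pr <- tiny_pair_problem()
  m <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  m0 <- m
  m0$W_out[] <- 0
  m0$b_out <- 0
  p <- predict(m0, pr$pairs, pr$struct, pr$ac, pr$ct)
  expect_equal(unique(p$prob), 0.5)
  expect_equal(unique(p$pred), 0L)     # 0.5 is not "higher than 0.5"

  # probability is monotone in the output bias
  m_hi <- m0
  m_hi$b_out <- 2
  expect_true(all(predict(m_hi, pr$pairs, pr$struct, pr$ac,
                          pr$ct)$prob > 0.5))
})

test_that("training validates classes and missing modalities", {
  pr <- tiny_pair_problem()
  onec <- pr$pairs
  onec$label <- 1L
  expect_error(ppi_train(onec, pr$struct, pr$ac, pr$ct, small_config()),
               class = "voxppi_error_validation")
  # a pair referencing an unknown protein names it
  bad <- pr$pairs
  bad$id_a[1] <- "zz99"
  err <- expect_error(
    ppi_train(bad, pr$struct, pr$ac, pr$ct, small_config()),
    class = "voxppi_error_validation")
  expect_match(conditionMessage(err), "zz99")
  m <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  expect_error(predict(m, pr$pairs, pr$struct, NULL, pr$ct),
               class = "voxppi_error_validation")
})

test_that("the autoencoders only ever see training-split proteins", {
  pr <- tiny_pair_problem()
  split <- train_test_split(pr$pairs, 0.25, seed = 4)
  m <- ppi_train(split$train, pr$struct, pr$ac, pr$ct, small_config())
  expect_true(all(m$train_ids %in%
                    c(split$train$id_a, split$train$id_b)))
  expect_equal(m$n_train_pairs, nrow(split$train))
})

test_that("tidy, glance and autoplot expose the training record", {
  pr <- tiny_pair_problem()
  m <- ppi_train(pr$pairs, pr$struct, pr$ac, pr$ct, small_config())
  expect_s3_class(tidy(m), "tbl_df")
  g <- glance(m)
  expect_equal(g$epochs, 30)
  expect_equal(g$fused_dim, 12)
  expect_s3_class(autoplot(m), "ggplot")
})
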