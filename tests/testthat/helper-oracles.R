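# Independent reference implementations used as oracles. These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals they check.

# lagged autocovariance by explicit double loop over positions
oracle_ac <- function(seq, lag, table) {
  chars <- strsplit(seq, "")[[1]]
  l <- length(chars)
  n_desc <- ncol(table)
  out <- numeric(n_desc * lag)
  pos <- 1
  for (n in seq_len(n_desc)) {
    vals <- table[chars, n]
    m_bar <- mean(vals)
    for (d in seq_len(lag)) {
      acc <- 0
      for (m in seq_len(l - d)) {
        acc <- acc + (vals[m] - m_bar) * (vals[m + d] - m_bar)
      }
      out[pos] <- acc / (l - d)
      pos <- pos + 1
    }
  }
  out
}

# conjoint-triad counts by enumerating every window against every triad
oracle_ct <- function(seq, clustering) {
  chars <- strsplit(seq, "")[[1]]
  counts <- integer(343)
  for (c1 in 1:7) for (c2 in 1:7) for (c3 in 1:7) {
    idx <- (c1 - 1) * 49 + (c2 - 1) * 7 + (c3 - 1) + 1
    for (w in seq_len(length(chars) - 2)) {
      win <- clustering[chars[w:(w + 2)]]
      if (win[1] == c1 && win[2] == c2 && win[3] == c3) {
        counts[idx] <- counts[idx] + 1
      }
    }
  }
  counts
}

# direct transliteration of the LSTM gate equations, scalar loops
oracle_lstm_step <- function(params, h_prev, C_prev, x) {
  sig <- function(v) 1 / (1 + exp(-v))
  z <- c(h_prev, x)
  hd <- length(h_prev)
  f <- i <- cc <- o <- C <- h <- numeric(hd)
  for (j in seq_len(hd)) {
    f[j] <- sig(sum(params$W_f[j, ] * z) + params$b_f[j])
    i[j] <- sig(sum(params$W_i[j, ] * z) + params$b_i[j])
    cc[j] <- tanh(sum(params$W_c[j, ] * z) + params$b_c[j])
    o[j] <- sig(sum(params$W_o[j, ] * z) + params$b_o[j])
    C[j] <- f[j] * C_prev[j] + i[j] * cc[j]
    h[j] <- o[j] * tanh(C[j])
  }
  list(h = h, C = C)
}

# AUROC as the exhaustive mean over all positive/negative comparisons
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Welch's t-test from the closed-form definition
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# small helpers shared by tests
random_seq <- function(n, seed) {
  withr::with_seed(seed,
                   paste(sample(voxppi::AA_ALPHABET, n, replace = TRUE),
                         collapse = ""))
}

tiny_trace <- function(n_res = 3, seed = 1) {
  voxppi::synth_backbone(n_res, seed = seed)$trace
}
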