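# Fixed-length sequence encodings: autocovariance (AC) and conjoint
# triad (CT).
#
# AC turns each of n physicochemical descriptor signals along the sequence
# into its lagged autocovariances (lags 1..lag), giving an n*lag vector
# (210 at the defaults n = 7, lag = 30). CT maps residues to 7
# physicochemical clusters and counts all length-3 cluster windows, giving
# a 7^3 = 343 count vector.

#' Column-standardize a descriptor table
#'
#' z-scores each descriptor column over the 20 amino acids, so that every
#' descriptor enters the autocovariance on a common scale.
#'
#' @param raw a 20 x n numeric matrix with amino-acid rownames
#' @return matrix of the same shape; each column has mean 0 and sd 1
#' @export
normalize_descriptors <- function(raw) {
  if (nrow(raw) != 20 || !all(AA_ALPHABET %in% rownames(raw))) {
    vox_abort("config",
              "descriptor table must have the 20 standard amino acids as rows")
  }
  if (any(!is.finite(raw))) {
    vox_abort("config", "descriptor table contains non-finite values")
  }
  sds <- apply(raw, 2, sd)
  if (any(sds == 0)) {
    vox_abort("degenerate_descriptor",
              sprintf("constant descriptor column(s): %s",
                      paste(colnames(raw)[sds == 0], collapse = ", ")))
  }
  scale(raw)[, , drop = FALSE]
}

check_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    vox_abort("validation",
              sprintf("sequence contains non-standard symbol(s): %s",
                      paste(bad, collapse = ", ")))
  }
  chars
}

#' Autocovariance encoding of a protein sequence
#'
#' For descriptor n and lag d, the encoding is
#' \deqn{AC_{d,n} = \frac{1}{l-d} \sum_{m=1}^{l-d}
#'   (P_{m,n} - \bar P_n)(P_{m+d,n} - \bar P_n)}
#' where \eqn{P_{m,n}} is the standardized descriptor value of residue m,
#' \eqn{l} the sequence length and \eqn{\bar P_n} the per-sequence mean of
#' descriptor n. The output is descriptor-major: all lags of descriptor 1,
#' then descriptor 2, and so on, length `ncol(table) * lag`.
#'
#' @param seq a protein sequence (character scalar over the 20-letter
#'   alphabet)
#' @param lag maximum lag (default 30)
#' @param table descriptor table; the shipped seven-property table
#'   ([ac_descriptor_table()]) standardized by [normalize_descriptors()]
#' @param literal_sum if `TRUE`, subtract the raw per-sequence descriptor
#'   sum instead of the mean inside the covariance. This reproduces a
#'   sum-instead-of-mean variant sometimes seen in print; values then grow
#'   with sequence length, so it exists for comparison only.
#' @return numeric vector of length `ncol(table) * lag`, named
#'   `<descriptor>_lag<d>`
#' @export
#' @examples
#' v <- ac_encode(strrep("MKVL", 20))
#' length(v)  # 210
ac_encode <- function(seq, lag = 30,
                      table = normalize_descriptors(ac_descriptor_table()),
                      literal_sum = FALSE) {
  chars <- check_sequence(seq)
  l <- length(chars)
  lag <- stopifnot_scalar_int(lag, "lag")
  if (lag < 1) vox_abort("config", "`lag` must be >= 1")
  if (l <= lag) {
    vox_abort("sequence_too_short",
              sprintf("sequence length %d must exceed lag %d", l, lag))
  }
  P <- table[chars, , drop = FALSE]            # l x n descriptor signal
  center <- if (literal_sum) colSums(P) else colMeans(P)
  D <- sweep(P, 2, center)                     # deviations per descriptor
  out <- matrix(0, nrow = lag, ncol = ncol(P))
  for (d in seq_len(lag)) {
    m <- seq_len(l - d)
    out[d, ] <- colSums(D[m, , drop = FALSE] * D[m + d, , drop = FALSE]) /
      (l - d)
  }
  nm <- colnames(table)
  if (is.null(nm)) nm <- paste0("d", seq_len(ncol(P)))
  setNames(as.numeric(out),
           paste0(rep(nm, each = lag), "_lag", rep(seq_len(lag), ncol(P))))
}

#' Conjoint-triad encoding of a protein sequence
#'
#' Residues are mapped to their 7-group cluster and every window of three
#' consecutive residues (sliding one residue at a time) is counted. Triad
#' (c1, c2, c3) occupies 0-based index (c1-1)*49 + (c2-1)*7 + (c3-1).
#'
#' @param seq a protein sequence (length >= 3)
#' @param clustering named map from amino acid to cluster 1..7
#'   (default [ct_clustering()])
#' @return integer vector of 343 window counts, named `c<c1><c2><c3>`;
#'   counts sum to `nchar(seq) - 2`
#' @export
#' @examples
#' sum(ct_encode("MKVLAAGH"))  # 6
ct_encode <- function(seq, clustering = ct_clustering()) {
  chars <- check_sequence(seq)
  cl <- validate_clustering(clustering)
  l <- length(chars)
  if (l < 3) {
    vox_abort("sequence_too_short",
              sprintf("sequence length %d is below 3", l))
  }
  c1 <- cl[chars[1:(l - 2)]]
  c2 <- cl[chars[2:(l - 1)]]
  c3 <- cl[chars[3:l]]
  idx <- (c1 - 1L) * 49L + (c2 - 1L) * 7L + (c3 - 1L) + 1L
  counts <- tabulate(idx, nbins = 343L)
  grid <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)[, 3:1]
  setNames(counts, sprintf("c%d%d%d", grid$c1, grid$c2, grid$c3))
}

#' Encode a table of sequences as a feature table
#'
#' Tidy wrapper applying [ac_encode()] or [ct_encode()] to every row of a
#' sequence tibble.
#'
#' @param seqs tibble with columns `id` and `seq` (as from [read_fasta()])
#' @param method `"ac"` or `"ct"`
#' @param ... passed to the underlying encoder
#' @return a feature table (tag `"AC"` or `"CT"`)
#' @export
encode_sequences <- function(seqs, method = c("ac", "ct"), ...) {
  method <- match.arg(method)
  fn <- switch(method, ac = ac_encode, ct = ct_encode)
  vecs <- lapply(seqs$seq, fn, ...)
  feature_table(seqs$id, lapply(vecs, as.numeric),
                tag = switch(method, ac = "AC", ct = "CT"))
}
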