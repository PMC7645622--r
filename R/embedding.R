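# Structural embedding: map each voxel channel to a fixed-length feature
# vector through a pluggable embedder contract, and build the per-pair
# 4-timestep sequences consumed by the LSTM classifier.
#
# An embedder is any object with an `embed(channel)` function returning
# `output_dim` finite values. The shipped stub embedder composes the
# 3-plane maximum-intensity-projection image with a seeded fixed random
# linear map: deterministic, download-free, and linear in the channel so
# occupancy and attribute signal survives into the embedding.

#' Project a voxel channel to a 3-plane 2D image
#'
#' Takes maximum-intensity projections of the l x l x l channel along x, y
#' and z and stacks them as the three planes of an l x l x 3 image,
#' optionally resized (nearest neighbor) to an embedder's expected spatial
#' size.
#'
#' @param channel an l x l x l numeric array
#' @param size output spatial size per axis (default: keep l)
#' @return a `size x size x 3` array
#' @export
channel_to_image <- function(channel, size = dim(channel)[1]) {
  proj <- list(
    apply(channel, c(2, 3), max),   # along x
    apply(channel, c(1, 3), max),   # along y
    apply(channel, c(1, 2), max)    # along z
  )
  l <- dim(channel)[1]
  img <- array(0, dim = c(size, size, 3))
  idx <- if (size == l) seq_len(l) else ceiling(seq_len(size) * l / size)
  for (k in 1:3) img[, , k] <- proj[[k]][idx, idx]
  img
}

#' Deterministic stub embedder
#'
#' A fixed random linear map from the flattened 3-plane projection image of
#' a channel to `output_dim` values, scaled by `1/sqrt(3 l^2)`. Given the
#' same seed the map — and hence every embedding — is reproducible across
#' sessions, which makes it the default embedder for tests and synthetic
#' experiments. A pretrained convolutional backbone can be plugged in
#' through the same contract via [new_embedder()].
#'
#' @param output_dim embedding length (default 2048)
#' @param seed seed for the fixed projection matrix
#' @param l spatial grid size the embedder expects (default 32)
#' @return an `embedder` object
#' @export
#' @examples
#' e <- stub_embedder(output_dim = 8, seed = 1)
#' length(e$embed(array(0, dim = c(32, 32, 32))))
stub_embedder <- function(output_dim = 2048, seed = 7, l = 32) {
  output_dim <- stopifnot_scalar_int(output_dim, "output_dim")
  d_in <- 3 * l * l
  W <- with_seed(seed,
                 matrix(rnorm(d_in * output_dim), nrow = output_dim,
                        ncol = d_in)) / sqrt(d_in)
  embed <- function(channel) {
    img <- channel_to_image(channel, size = l)
    as.numeric(W %*% as.numeric(img))
  }
  new_embedder(embed, output_dim = output_dim, deterministic = TRUE,
               name = sprintf("stub(seed=%d)", seed))
}

#' Construct an embedder satisfying the embedding contract
#'
#' @param embed function mapping an l x l x l channel array to a numeric
#'   vector of length `output_dim`
#' @param output_dim declared embedding length
#' @param deterministic whether identical inputs give identical outputs
#' @param name display name
#' @return an `embedder` object
#' @export
new_embedder <- function(embed, output_dim, deterministic = TRUE,
                         name = "custom") {
  structure(list(embed = embed,
                 output_dim = stopifnot_scalar_int(output_dim, "output_dim"),
                 deterministic = isTRUE(deterministic), name = name),
            class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("<embedder %s, output_dim=%d, deterministic=%s>\n",
              x$name, x$output_dim, x$deterministic))
  invisible(x)
}

#' Embed every channel of a voxel grid
#'
#' Applies the embedder to the binary channel and each attribute channel in
#' the fixed order binary, hydropathy, isoelectric, charge.
#'
#' @param grid a `voxel_grid`
#' @param embedder an `embedder`
#' @return a 4 x output_dim numeric matrix, rownames in channel order
#' @export
embed_protein <- function(grid, embedder) {
  channels <- c(list(binary = grid$binary), grid$channels)
  out <- matrix(0, nrow = length(channels), ncol = embedder$output_dim)
  rownames(out) <- names(channels)
  for (i in seq_along(channels)) {
    v <- embedder$embed(channels[[i]])
    if (length(v) != embedder$output_dim || any(!is.finite(v))) {
      vox_abort("contract",
                sprintf(
                  "embedder '%s' returned %d values (expected %d finite)",
                  embedder$name, length(v), embedder$output_dim))
    }
    out[i, ] <- v
  }
  out
}

#' Embed a set of voxel grids into a structural feature table
#'
#' Each protein's 4 channel embeddings are flattened channel-major into one
#' vector of length `4 * output_dim` (reshaped back by
#' [build_pair_sequence()]).
#'
#' @param grids named list of `voxel_grid` objects (names are protein ids)
#' @param embedder an `embedder`
#' @return a feature table with tag `"structural"`
#' @export
embed_proteins <- function(grids, embedder) {
  vecs <- lapply(grids, function(g) {
    as.numeric(t(embed_protein(g, embedder)))
  })
  feature_table(names(grids), vecs, tag = "structural")
}

# inverse of the channel-major flattening in embed_proteins
structural_to_matrix <- function(vec) {
  d <- length(vec) / 4
  if (d != floor(d)) {
    vox_abort("contract", "structural vector length is not divisible by 4")
  }
  matrix(vec, nrow = 4, ncol = d, byrow = TRUE)
}

#' Build the 4-timestep pair sequence
#'
#' Timestep t is the concatenation of protein A's and protein B's
#' embeddings of channel t (A first), for the channel order binary,
#' hydropathy, isoelectric, charge. With 2048-dim embeddings each step has
#' 4096 elements.
#'
#' @param vecs_a,vecs_b 4 x d embedding matrices (see [embed_protein()])
#' @return a 4 x 2d matrix; row t is timestep t
#' @export
build_pair_sequence <- function(vecs_a, vecs_b) {
  if (!is.matrix(vecs_a) || !is.matrix(vecs_b) ||
      nrow(vecs_a) != 4 || nrow(vecs_b) != 4 ||
      ncol(vecs_a) != ncol(vecs_b)) {
    vox_abort("contract",
              "pair inputs must be 4 x d matrices of equal width")
  }
  cbind(vecs_a, vecs_b)
}
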