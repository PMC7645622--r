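# Voxelization of a protein backbone into one binary occupancy channel and
# three residue-attribute channels (hydropathy, isoelectric point, charge).
#
# Pipeline: attach per-residue attribute values to the backbone atoms,
# densify the trace by linear interpolation between consecutive atoms,
# centre on the origin and scale by lambda = floor(l/2 - 1) / R_max, assign
# points to nearest voxels, then remove voxels with no occupied neighbor.

#' Voxelizer configuration
#'
#' @param p interpolation points inserted between consecutive backbone
#'   atoms (default 5)
#' @param l cubic grid size in voxels per axis (default 32, must be even)
#' @param r_max radius in Angstrom of the sphere mapped into the grid
#'   (default 40); the scale factor is
#'   `lambda = floor(l/2 - 1) / r_max` (0.375 at the defaults)
#' @param attributes ordered names of the residue-attribute channels
#' @param neighbor_connectivity 6 (face-adjacent) or 26 for the
#'   isolated-voxel pruning step
#' @param stepwise_attributes if `TRUE`, interpolated points inherit the
#'   attribute values of the preceding atom instead of linearly
#'   interpolated values
#' @return a `voxel_config` list with the derived `lambda`
#' @export
#' @examples
#' voxel_config()$lambda  # 0.375
voxel_config <- function(p = 5, l = 32, r_max = 40,
                         attributes = c("hydropathy", "isoelectric",
                                        "charge"),
                         neighbor_connectivity = 6,
                         stepwise_attributes = FALSE) {
  p <- stopifnot_scalar_int(p, "p")
  l <- stopifnot_scalar_int(l, "l")
  if (p < 0) vox_abort("config", "`p` must be >= 0")
  if (l < 2 || l %% 2 != 0) vox_abort("config", "`l` must be even and >= 2")
  if (!is.numeric(r_max) || r_max <= 0) {
    vox_abort("config", "`r_max` must be > 0")
  }
  if (!neighbor_connectivity %in% c(6, 26)) {
    vox_abort("config", "`neighbor_connectivity` must be 6 or 26")
  }
  structure(
    list(p = p, l = l, r_max = r_max, attributes = attributes,
         neighbor_connectivity = neighbor_connectivity,
         stepwise_attributes = isTRUE(stepwise_attributes),
         lambda = floor(l / 2 - 1) / r_max),
    class = "voxel_config")
}

#' Attach residue attribute values to a backbone trace
#'
#' Every backbone atom inherits its parent residue's value for each
#' configured attribute.
#'
#' @param trace a `backbone_trace` (see [read_pdb_backbone()])
#' @param tables named list of per-amino-acid value vectors, one per
#'   attribute (default [voxel_attribute_tables()])
#' @return an attributed point cloud: tibble with `x`, `y`, `z` and one
#'   column per attribute
#' @export
attach_attributes <- function(trace, tables = voxel_attribute_tables()) {
  cloud <- tibble(x = trace$x, y = trace$y, z = trace$z)
  aa <- trace[["residue_1"]]
  if (is.null(aa)) {
    aa <- unname(AA_THREE_TO_ONE[trace$residue_name])
  }
  missing <- unique(trace$residue_name[is.na(aa)])
  if (length(missing) > 0) {
    vox_abort("lookup",
              sprintf("residue(s) missing from attribute tables: %s",
                      paste(missing, collapse = ", ")))
  }
  for (attr_name in names(tables)) {
    vals <- tables[[attr_name]][aa]
    if (anyNA(vals)) {
      vox_abort("lookup",
                sprintf("residue(s) missing from '%s' table: %s",
                        attr_name,
                        paste(unique(aa[is.na(vals)]), collapse = ", ")))
    }
    cloud[[attr_name]] <- unname(vals)
  }
  cloud
}

#' Linearly interpolate points along a point cloud
#'
#' Between each consecutive pair (A_i, A_(i+1)), `p` points are inserted at
#' ((p - k + 1) A_i + k A_(i+1)) / (p + 1) for k = 1..p, applied to the
#' coordinates and (by default) the attribute columns alike. Output order
#' is A_1, its p interpolants, A_2, ...; a cloud of N points grows to
#' N + (N - 1) p.
#'
#' @param cloud attributed point cloud (tibble with `x`, `y`, `z` and
#'   attribute columns)
#' @param p number of interpolants per consecutive pair
#' @param stepwise_attributes if `TRUE`, interpolants copy the preceding
#'   point's attribute values instead of interpolating them
#' @return interpolated point cloud
#' @export
interpolate_points <- function(cloud, p = 5, stepwise_attributes = FALSE) {
  p <- stopifnot_scalar_int(p, "p")
  if (p < 0) vox_abort("config", "`p` must be >= 0")
  n <- nrow(cloud)
  if (n < 1) vox_abort("validation", "point cloud is empty")
  if (p == 0 || n == 1) return(cloud)

  m <- as.matrix(cloud)
  is_coord <- colnames(m) %in% c("x", "y", "z")
  # fractional position of each output point along the chain of segments:
  # original point i sits at i, the k-th interpolant after it at
  # i + k / (p + 1)
  frac <- seq_len(p) / (p + 1)
  out_rows <- vector("list", 2L * n - 1L)
  for (i in seq_len(n - 1)) {
    out_rows[[2 * i - 1]] <- m[i, , drop = FALSE]
    a <- m[i, ]
    b <- m[i + 1, ]
    interp <- outer(1 - frac, a) + outer(frac, b)
    if (stepwise_attributes) {
      interp[, !is_coord] <- matrix(rep(a[!is_coord], each = p), nrow = p)
    }
    out_rows[[2 * i]] <- interp
  }
  out_rows[[2 * n - 1]] <- m[n, , drop = FALSE]
  out <- do.call(rbind, out_rows)
  colnames(out) <- colnames(m)
  as_tibble(as.data.frame(out))
}

#' Centre a point cloud on the origin and apply the grid scale
#'
#' Coordinates are shifted to zero centroid and multiplied by
#' `lambda = floor(l/2 - 1) / r_max`; attribute columns are unchanged.
#'
#' @param cloud attributed point cloud
#' @param cfg a [voxel_config()]
#' @return scaled point cloud in grid units
#' @export
center_and_scale <- function(cloud, cfg = voxel_config()) {
  if (nrow(cloud) < 1) vox_abort("validation", "point cloud is empty")
  for (ax in c("x", "y", "z")) {
    cloud[[ax]] <- (cloud[[ax]] - mean(cloud[[ax]])) * cfg$lambda
  }
  cloud
}

new_voxel_grid <- function(binary, channels, config) {
  structure(list(binary = binary, channels = channels, config = config),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, %d occupied, channels: %s>\n",
              x$config$l, x$config$l, x$config$l, sum(x$binary),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Assign a scaled point cloud to voxels
#'
#' Each point lands in the voxel indexed by its coordinate rounded half
#' away from zero, offset by l/2 (so the origin maps to 0-based index
#' (l/2, l/2, l/2)). Occupied voxels get binary 1; each attribute channel
#' holds the mean attribute value of the points in the voxel. Points whose
#' index falls outside the grid are dropped with a warning reporting the
#' count.
#'
#' @param cloud centred, scaled point cloud
#' @param cfg a [voxel_config()]
#' @return a `voxel_grid`: list with `binary` (l^3 array of 0/1),
#'   `channels` (named list of l^3 arrays) and `config`
#' @export
assign_voxels <- function(cloud, cfg = voxel_config()) {
  l <- cfg$l
  # 1-based array index: 0-based round(coord) + l/2, plus 1
  ix <- round_half_away(cloud$x) + l / 2 + 1
  iy <- round_half_away(cloud$y) + l / 2 + 1
  iz <- round_half_away(cloud$z) + l / 2 + 1
  inside <- ix >= 1 & ix <= l & iy >= 1 & iy <= l & iz >= 1 & iz <= l
  n_dropped <- sum(!inside)
  if (n_dropped == nrow(cloud)) {
    vox_abort("empty_grid", "all points fall outside the voxel grid")
  }
  if (n_dropped > 0) {
    vox_warn("points_dropped",
             sprintf("%d point(s) outside the %d^3 grid were dropped",
                     n_dropped, l))
  }
  lin <- (ix[inside] - 1) + (iy[inside] - 1) * l + (iz[inside] - 1) * l * l + 1
  binary <- array(0, dim = c(l, l, l))
  binary[unique(lin)] <- 1

  attrs <- intersect(cfg$attributes, colnames(cloud))
  counts <- tabulate(lin, nbins = l^3)
  channels <- lapply(setNames(attrs, attrs), function(a) {
    sums <- numeric(l^3)
    acc <- rowsum(cloud[[a]][inside], group = lin)
    sums[as.integer(rownames(acc))] <- acc[, 1]
    ch <- array(0, dim = c(l, l, l))
    occ <- counts > 0
    ch[occ] <- sums[occ] / counts[occ]
    ch
  })
  new_voxel_grid(binary, channels, cfg)
}

#' Remove isolated voxels
#'
#' Clears every occupied voxel that has no occupied neighbor under the
#' chosen connectivity (6 = face-adjacent, 26 = full cube). Removal
#' decisions are made against the input occupancy in a single pass, so the
#' operation is idempotent.
#'
#' @param grid a `voxel_grid`
#' @param connectivity 6 or 26 (default taken from the grid's config)
#' @return the pruned `voxel_grid`
#' @export
prune_isolated <- function(grid,
                           connectivity = grid$config$neighbor_connectivity) {
  if (!connectivity %in% c(6, 26)) {
    vox_abort("config", "`connectivity` must be 6 or 26")
  }
  b <- grid$binary
  l <- dim(b)[1]
  if (connectivity == 6) {
    offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  }
  # count occupied neighbors by shifting a zero-padded copy
  pad <- array(0, dim = dim(b) + 2)
  pad[2:(l + 1), 2:(l + 1), 2:(l + 1)] <- b
  nb <- array(0, dim = dim(b))
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    nb <- nb + pad[2:(l + 1) + o[1], 2:(l + 1) + o[2], 2:(l + 1) + o[3]]
  }
  isolated <- b == 1 & nb == 0
  grid$binary[isolated] <- 0
  grid$channels <- lapply(grid$channels, function(ch) {
    ch[isolated] <- 0
    ch
  })
  grid
}

#' Voxelize a protein backbone
#'
#' Full composition: [attach_attributes()] -> [interpolate_points()] ->
#' [center_and_scale()] -> [assign_voxels()] -> [prune_isolated()].
#' Yields one binary occupancy channel plus one channel per configured
#' residue attribute (hydropathy, isoelectric point, charge by default).
#'
#' @param trace a `backbone_trace`
#' @param cfg a [voxel_config()]
#' @param tables attribute tables (default [voxel_attribute_tables()])
#' @return a `voxel_grid`
#' @export
#' @examples
#' tr <- synth_backbone(30, seed = 1)$trace
#' voxelize_protein(tr)
voxelize_protein <- function(trace, cfg = voxel_config(),
                             tables = voxel_attribute_tables()) {
  if (nrow(trace) < 1) vox_abort("empty_structure", "trace has no atoms")
  tables <- tables[cfg$attributes]
  cloud <- attach_attributes(trace, tables)
  cloud <- interpolate_points(cloud, cfg$p,
                              stepwise_attributes = cfg$stepwise_attributes)
  cloud <- center_and_scale(cloud, cfg)
  grid <- assign_voxels(cloud, cfg)
  prune_isolated(grid)
}
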