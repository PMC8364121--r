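# Cube-node extraction: tile the grey-matter volume into non-overlapping
# 3x3x3 voxel blocks and keep the blocks that contain grey matter.

#' Partition a grey-matter volume into cube nodes
#'
#' Tiles the volume into non-overlapping 3x3x3-voxel cubes (6x6x6 mm^3 at
#' 2 mm resolution) in raster order and keeps as network nodes the cubes
#' that contain grey matter.  A cube is retained when it has at least one
#' voxel with positive intensity and the fraction of its 27 voxels with
#' positive intensity is at least `min_gm_fraction`.  Each retained cube
#' carries its atlas label — the majority label among its positive-intensity
#' voxels (background label 0 is ignored in the vote; ties go to the
#' smallest region id) — and its grey-matter volume, the sum of intensity
#' over the 27 voxels.
#'
#' Volumes whose dimensions are not multiples of 3 are zero-padded at the
#' high end of each axis before tiling.
#'
#' @param gm_image 3D numeric array of grey-matter intensities (>= 0).
#' @param atlas_labels Optional 3D integer array of the same dimensions;
#'   0 denotes background.  When `NULL`, all cubes get label `NA`.
#' @param min_gm_fraction Minimum fraction of the 27 voxels that must have
#'   positive intensity for the cube to become a node (default 0).
#' @return An object of class `gmnet_cubes`: a list with `values`
#'   (27 x n matrix of intensities, columns in raster cube order), `origin`
#'   (n x 3 matrix of 0-based voxel coordinates of each cube's lowest
#'   corner, all multiples of 3), `label`, `gm_volume`, and `index`.
#' @examples
#' img <- array(runif(6 * 6 * 6), c(6, 6, 6))
#' cubes <- partition_into_cubes(img)
#' ncol(cubes$values)  # 8 cubes tile a 6x6x6 volume
#' @export
partition_into_cubes <- function(gm_image, atlas_labels = NULL,
                                 min_gm_fraction = 0) {
  if (length(dim(gm_image)) != 3L)
    stop("'gm_image' must be a 3D array", call. = FALSE)
  if (!is.null(atlas_labels) && !identical(dim(gm_image), dim(atlas_labels)))
    stop("'gm_image' and 'atlas_labels' must share dimensions", call. = FALSE)
  stopifnot_scalar_number(min_gm_fraction, "min_gm_fraction", 0, 1)

  dm <- dim(gm_image)
  pad <- (3L - dm %% 3L) %% 3L
  if (any(pad > 0L)) {
    nd <- dm + pad
    padded <- array(0, nd)
    padded[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- gm_image
    gm_image <- padded
    if (!is.null(atlas_labels)) {
      pl <- array(0L, nd)
      pl[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- atlas_labels
      atlas_labels <- pl
    }
    dm <- nd
  }
  nb <- dm %/% 3L

  n_total <- prod(nb)
  values <- matrix(0, 27L, n_total)
  labels <- rep(NA_integer_, n_total)
  origin <- matrix(0L, n_total, 3L)
  k <- 0L
  for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[1])) {
    k <- k + 1L
    xs <- (bx - 1L) * 3L + 1:3; ys <- (by - 1L) * 3L + 1:3; zs <- (bz - 1L) * 3L + 1:3
    block <- gm_image[xs, ys, zs]
    values[, k] <- as.vector(block)
    origin[k, ] <- c(xs[1], ys[1], zs[1]) - 1L
    if (!is.null(atlas_labels)) {
      lab <- as.vector(atlas_labels[xs, ys, zs])[as.vector(block) > 0]
      lab <- lab[lab != 0L]
      if (length(lab)) {
        tab <- table(lab)
        winners <- as.integer(names(tab)[tab == max(tab)])
        labels[k] <- min(winners)       # tie -> smallest region id
      } else labels[k] <- 0L
    }
  }

  frac <- colMeans(values > 0)
  keep <- frac > 0 & frac >= min_gm_fraction
  structure(list(
    values = values[, keep, drop = FALSE],
    origin = origin[keep, , drop = FALSE],
    label = labels[keep],
    gm_volume = colSums(values[, keep, drop = FALSE]),
    index = seq_len(sum(keep))
  ), class = "gmnet_cubes")
}

#' @export
print.gmnet_cubes <- function(x, ...) {
  cat(sprintf("gmnet cube set: %d nodes (3x3x3 voxels each)\n",
              length(x$index)))
  if (any(!is.na(x$label)))
    cat(sprintf("  atlas regions represented: %d\n",
                length(unique(x$label[!is.na(x$label) & x$label > 0]))))
  invisible(x)
}
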