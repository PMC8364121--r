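# Discrete rotations of the 3x3x3 voxel cube.
#
# Cube intensities are stored as length-27 vectors in raster order (the
# first grid axis varies fastest, matching R's array linearisation).
# A rotation of the cube is realised as a permutation of those 27 slots:
# the continuous rotation is applied to the voxel-centre coordinates
# (-1, 0, 1 along each axis) and each rotated centre is snapped to its
# nearest grid point.  Only maps that remain bijections of the grid are
# kept, so every retained rotation is a genuine permutation.

rotations_cache <- new.env(parent = emptyenv())

rot3 <- function(axis, angle) {
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Rotation permutation set for 3x3x3 cube nodes
#'
#' Enumerates all distinct spatial rotations of a 3x3x3 voxel cube obtained
#' by composing rotations about the three grid axes in multiples of 45
#' degrees.  Each composed rotation is realised on the discrete grid by
#' mapping voxel centres and snapping to the nearest grid point; maps that
#' collapse two voxels onto one are discarded, and duplicate permutations
#' are removed.  The resulting set contains the identity, is closed under
#' inverse, and has exactly 96 members on this grid.
#'
#' Maximising the Pearson correlation between two cubes over this set makes
#' the cube similarity measure insensitive to local cortical orientation:
#' two patches with the same intensity pattern in different orientations
#' still score highly.
#'
#' @return An integer matrix with 27 rows; each column is a permutation of
#'   `1:27` giving, for every slot of the rotated cube, the source slot in
#'   the unrotated cube.  The first column is the identity.
#' @examples
#' rots <- rotation_set()
#' ncol(rots)            # 96 distinct rotations
#' all(rots[, 1] == 1:27) # identity comes first
#' @export
rotation_set <- function() {
  if (!is.null(rotations_cache$perms)) return(rotations_cache$perms)
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  angles <- (0:7) * pi / 4
  seen <- character()
  perms <- list()
  for (a in angles) for (b in angles) for (cc in angles) {
    R <- rot3("z", a) %*% rot3("y", b) %*% rot3("x", cc)
    mapped <- round(coords %*% t(R))
    mapped[mapped > 1] <- 1; mapped[mapped < -1] <- -1
    idx <- (mapped[, 1] + 1) + (mapped[, 2] + 1) * 3 + (mapped[, 3] + 1) * 9 + 1
    if (length(unique(idx)) != 27L) next
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    perms[[length(perms) + 1L]] <- as.integer(idx)
  }
  out <- do.call(cbind, perms)
  # identity first (deterministic ordering for reproducibility)
  id <- which(vapply(seq_len(ncol(out)), function(j) all(out[, j] == 1:27),
                     logical(1)))
  out <- cbind(out[, id, drop = FALSE], out[, -id, drop = FALSE])
  storage.mode(out) <- "integer"
  rotations_cache$perms <- out
  out
}

# standardise 27-vector columns so that crossprod of two standardised
# columns is exactly their Pearson correlation; zero-variance columns
# become all-zero (correlation-0 convention for degenerate cubes).
standardize_cube_columns <- function(values) {
  values <- as.matrix(values)
  mu <- colMeans(values)
  centred <- sweep(values, 2L, mu)
  ss <- sqrt(colSums(centred^2))
  ok <- ss > 0
  centred[, ok] <- sweep(centred[, ok, drop = FALSE], 2L, ss[ok], "/")
  centred[, !ok] <- 0
  centred
}

#' Maximum rotated correlation between two cube nodes
#'
#' Computes the Pearson correlation between two 27-voxel cubes for every
#' rotation in the discrete rotation set and returns the maximum.  If
#' either cube has zero intensity variance (a flat patch) the correlation
#' is defined as 0, which guarantees such nodes never survive a positive
#' binarisation threshold.
#'
#' @param cube_a,cube_b Numeric vectors of length 27 (raster order).
#' @param rotations Integer permutation matrix from [rotation_set()].
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' set.seed(1)
#' a <- rnorm(27)
#' max_rotated_correlation(a, a)  # 1: identity rotation aligns a with itself
#' @export
max_rotated_correlation <- function(cube_a, cube_b, rotations = rotation_set()) {
  if (length(cube_a) != 27L || length(cube_b) != 27L)
    stop("cube value vectors must have length 27", call. = FALSE)
  za <- standardize_cube_columns(matrix(cube_a, ncol = 1L))[, 1L]
  zb <- standardize_cube_columns(matrix(cube_b, ncol = 1L))[, 1L]
  if (all(za == 0) || all(zb == 0)) return(0)
  best <- -1
  for (j in seq_len(ncol(rotations))) {
    r <- sum(za * zb[rotations[, j]])
    if (r > best) best <- r
  }
  min(max(best, -1), 1)
}
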