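# User-facing fitting function: grey-matter image -> binarised network.

#' Extract a single-subject grey-matter network
#'
#' Builds the subject's grey-matter similarity network end-to-end: the
#' volume is tiled into 3x3x3-voxel cube nodes, all pairwise Pearson
#' correlations are maximised over the discrete 45-degree rotation set,
#' a binarisation threshold is calibrated by within-cube permutation so
#' that at most a fraction `alpha` of connections are expected to be
#' spurious, and the similarity matrix is binarised at that threshold.
#'
#' @param gm_image 3D numeric array of grey-matter intensities.
#' @param atlas_labels Optional co-registered 3D integer label array
#'   (0 = background) used for regional analyses.
#' @param alpha Nominal spurious-edge risk for threshold calibration
#'   (default 0.05).
#' @param n_permutations Null sample size for the calibration
#'   (default 1000).
#' @param min_gm_fraction Minimum fraction of positive-intensity voxels for
#'   a cube to become a node (default 0: any cube containing grey matter).
#' @param seed Integer seed for the permutation calibration.
#' @param keep_similarity Keep the dense similarity matrix in the returned
#'   object (default `TRUE`; set `FALSE` to save memory on large volumes).
#' @return An object of class `gmnet` with components `cubes`
#'   (`gmnet_cubes`), `similarity` (or `NULL`), `threshold`
#'   (`gmnet_threshold`), `adjacency` (0/1 matrix), and `call`.
#'   Use [summary()] to obtain global and regional graph metrics.
#' @examples
#' img <- simulate_noise_image(c(9, 9, 9), seed = 1)
#' net <- gmnet(img, n_permutations = 200, seed = 1)
#' net
#' @seealso [compute_global_metrics()], [compute_regional_metrics()]
#' @export
gmnet <- function(gm_image, atlas_labels = NULL, alpha = 0.05,
                  n_permutations = 1000L, min_gm_fraction = 0,
                  seed = 1L, keep_similarity = TRUE) {
  cubes <- partition_into_cubes(gm_image, atlas_labels, min_gm_fraction)
  if (length(cubes$index) < 2L)
    stop("fewer than 2 grey-matter cubes: network calculation failure",
         call. = FALSE)
  rots <- rotation_set()
  sim <- build_similarity_matrix(cubes, rots)
  thr <- estimate_binarization_threshold(cubes, rots, alpha = alpha,
                                         n_permutations = n_permutations,
                                         seed = seed)
  adj <- binarize(sim, thr)
  structure(list(
    cubes = cubes,
    similarity = if (keep_similarity) sim else NULL,
    threshold = thr,
    adjacency = adj,
    call = match.call()
  ), class = "gmnet")
}

#' @export
print.gmnet <- function(x, ...) {
  n <- nrow(x$adjacency)
  e <- sum(x$adjacency) / 2
  cat("Single-subject grey-matter network\n")
  cat(sprintf("  nodes: %d cube(s) of 3x3x3 voxels\n", n))
  cat(sprintf("  edges: %d (density %.3f)\n", e,
              if (n > 1) 2 * e / (n * (n - 1)) else NA_real_))
  cat(sprintf("  threshold: r > %.4f (alpha = %g, %d permutations)\n",
              x$threshold$threshold, x$threshold$alpha,
              x$threshold$n_permutations))
  invisible(x)
}

#' Summarise a grey-matter network
#'
#' Computes the global graph measures (size, mean degree, density,
#' clustering, path length) together with the small-world normalisation
#' against degree-preserving random reference networks, and — when atlas
#' labels are available — the per-region nodal averages.
#'
#' @param object A `gmnet` object.
#' @param n_reference Number of randomised reference networks (default 5).
#' @param seed Seed for the reference-network randomisation.
#' @param regional Compute regional metrics when labels are present
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A `summary.gmnet` list with elements `global`
#'   (`gmnet_global_metrics`) and `regional` (data frame or `NULL`).
#' @export
summary.gmnet <- function(object, n_reference = 5L, seed = 1L,
                          regional = TRUE, ...) {
  glob <- compute_global_metrics(object$adjacency, n_reference = n_reference,
                                 seed = seed)
  reg <- NULL
  if (regional && any(!is.na(object$cubes$label)))
    reg <- compute_regional_metrics(object$adjacency, object$cubes$label,
                                    object$cubes$gm_volume)
  structure(list(global = glob, regional = reg), class = "summary.gmnet")
}

#' @export
print.summary.gmnet <- function(x, ...) {
  print(x$global)
  if (!is.null(x$regional)) {
    cat("\nRegional nodal averages:\n")
    print(x$regional, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot a grey-matter network
#'
#' Displays the binarised adjacency matrix (nodes in raster cube order)
#' and the node degree distribution.
#'
#' @param x A `gmnet` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gmnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::image(x$adjacency, col = c("white", "grey20"), axes = FALSE,
                  main = "Adjacency", ...)
  graphics::hist(node_degrees(x$adjacency), main = "Degree distribution",
                 xlab = "degree", col = "grey70", border = "white")
  invisible(x)
}
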