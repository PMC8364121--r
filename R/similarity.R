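# Similarity matrix construction and permutation-calibrated binarisation.

#' Rotation-maximised similarity matrix
#'
#' Computes, for every pair of cube nodes, the maximum Pearson correlation
#' over the discrete rotation set, yielding the subject's grey-matter
#' similarity matrix.  Self-connections are set to zero.  Because the
#' rotation set is closed under inverse and Pearson correlation is
#' symmetric in its arguments, the matrix is exactly symmetric.
#'
#' @param cubes A `gmnet_cubes` object from [partition_into_cubes()], or a
#'   27 x n numeric matrix of cube intensities.
#' @param rotations Integer permutation matrix from [rotation_set()].
#' @return An n x n symmetric numeric matrix with zero diagonal and
#'   off-diagonal entries in `[-1, 1]`.
#' @export
build_similarity_matrix <- function(cubes, rotations = rotation_set()) {
  values <- if (inherits(cubes, "gmnet_cubes")) cubes$values else as.matrix(cubes)
  if (nrow(values) != 27L)
    stop("cube values must be a 27 x n matrix", call. = FALSE)
  n <- ncol(values)
  if (n < 2L) stop("need at least 2 cubes to build a similarity matrix",
                   call. = FALSE)
  z <- standardize_cube_columns(values)
  sim <- matrix(-1, n, n)
  for (j in seq_len(ncol(rotations))) {
    s <- crossprod(z, z[rotations[, j], , drop = FALSE])
    sim <- pmax(sim, s)
  }
  # degenerate (zero-variance) cubes: correlation 0 by convention
  flat <- colSums(z != 0) == 0L
  if (any(flat)) { sim[flat, ] <- 0; sim[, flat] <- 0 }
  sim <- pmax(sim, t(sim))          # exact symmetry
  sim[sim > 1] <- 1; sim[sim < -1] <- -1
  diag(sim) <- 0
  sim
}

#' Permutation-calibrated binarisation threshold
#'
#' Calibrates the correlation cut-off used to binarise a similarity matrix
#' so that the chance of spurious (noise-driven) connections entering the
#' network is held at `alpha`.  A null distribution of rotation-maximised
#' correlations is built by repeatedly drawing pairs of the subject's own
#' cubes, independently shuffling the 27 intensities within each cube
#' (which destroys spatial structure while preserving each cube's intensity
#' distribution), and recording the rotation-maximised correlation of the
#' shuffled pair.  The threshold is the empirical `1 - alpha/M` quantile of
#' this null sample, where `M = n(n-1)/2` is the number of distinct node
#' pairs — a multiple-comparison-corrected per-edge significance level.
#'
#' @param cubes `gmnet_cubes` object or 27 x n value matrix.
#' @param rotations Integer permutation matrix from [rotation_set()].
#' @param alpha Nominal network-wise spurious-edge risk, in (0, 1).
#'   Default 0.05.
#' @param n_permutations Null sample size (>= 100; default 1000).
#' @param seed Integer seed; the calibration is deterministic given it.
#' @return An object of class `gmnet_threshold` with fields `threshold`,
#'   `alpha`, `n_permutations`, `n_pairs`, `per_edge_level`, `null_sample`
#'   (sorted), `null_quantiles`, and `seed`.
#' @export
estimate_binarization_threshold <- function(cubes, rotations = rotation_set(),
                                            alpha = 0.05,
                                            n_permutations = 1000L,
                                            seed = 1L) {
  values <- if (inherits(cubes, "gmnet_cubes")) cubes$values else as.matrix(cubes)
  n <- ncol(values)
  if (n < 2L) stop("need at least 2 cubes", call. = FALSE)
  stopifnot_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (n_permutations < 100L) stop("'n_permutations' must be >= 100", call. = FALSE)

  null_sample <- with_seed(seed, {
    ia <- sample.int(n, n_permutations, replace = TRUE)
    ib <- sample.int(n, n_permutations, replace = TRUE)
    # independent within-cube shuffles
    A <- matrix(0, 27L, n_permutations)
    B <- matrix(0, 27L, n_permutations)
    for (k in seq_len(n_permutations)) {
      A[, k] <- values[sample.int(27L), ia[k]]
      B[, k] <- values[sample.int(27L), ib[k]]
    }
    za <- standardize_cube_columns(A)
    zb <- standardize_cube_columns(B)
    best <- rep(-1, n_permutations)
    for (j in seq_len(ncol(rotations)))
      best <- pmax(best, colSums(za * zb[rotations[, j], , drop = FALSE]))
    flat <- colSums(za != 0) == 0L | colSums(zb != 0) == 0L
    best[flat] <- 0
    pmin(pmax(best, -1), 1)
  })

  sorted <- sort(null_sample)
  n_pairs <- n * (n - 1) / 2
  p_edge <- alpha / n_pairs                 # per-edge level after correction
  q <- sorted[min(length(sorted), max(1L, ceiling((1 - p_edge) * length(sorted))))]
  thr <- min(max(q, .Machine$double.eps), 1)

  structure(list(
    threshold = thr,
    alpha = alpha,
    n_permutations = as.integer(n_permutations),
    n_pairs = n_pairs,
    per_edge_level = p_edge,
    null_sample = sorted,
    null_quantiles = quantile(sorted, c(0.5, 0.9, 0.95, 0.99, 1)),
    seed = as.integer(seed)
  ), class = "gmnet_threshold")
}

#' @export
print.gmnet_threshold <- function(x, ...) {
  cat(sprintf(
    "gmnet binarisation threshold: r > %.4f\n  alpha = %g over %s node pairs (per-edge level %.3g)\n  null sample: %d within-cube permutations, seed %d\n",
    x$threshold, x$alpha, format(x$n_pairs, big.mark = ","),
    x$per_edge_level, x$n_permutations, x$seed))
  invisible(x)
}

#' Binarise a similarity matrix
#'
#' An edge is present when the rotation-maximised correlation strictly
#' exceeds the threshold.  Because the threshold is positive, only positive
#' correlations can contribute connections.
#'
#' @param similarity Symmetric similarity matrix with zero diagonal.
#' @param threshold Positive correlation cut-off, or a `gmnet_threshold`.
#' @return An n x n symmetric 0/1 integer matrix with zero diagonal.
#' @export
binarize <- function(similarity, threshold) {
  if (inherits(threshold, "gmnet_threshold")) threshold <- threshold$threshold
  stopifnot_scalar_number(threshold, "threshold", 0, strict_lower = TRUE)
  adj <- (similarity > threshold) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  adj
}
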