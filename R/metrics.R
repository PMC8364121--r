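# Global and regional graph measures with small-world normalisation.
# Standard graph algorithms are delegated to igraph; the conventions
# (degree-<2 clustering contributes 0, disconnected pairs excluded from
# path length, ratio-of-means normalisation) are fixed here.

as_adj_matrix <- function(adj) {
  if (inherits(adj, "gmnet")) adj <- adj$adjacency
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square", call. = FALSE)
  adj
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(as_adj_matrix(adj), mode = "undirected",
                                      diag = FALSE)
}

#' Node degrees
#'
#' @param adj 0/1 adjacency matrix (or a `gmnet` object).
#' @return Integer vector of per-node degrees.
#' @export
node_degrees <- function(adj) {
  as.integer(igraph::degree(as_igraph(adj)))
}

#' Mean clustering coefficient
#'
#' Watts-Strogatz clustering: per node, the fraction of its neighbour
#' pairs that are themselves connected; nodes with degree < 2 contribute 0.
#' The global value is the unweighted mean over all nodes.
#'
#' @inheritParams node_degrees
#' @return Mean clustering coefficient in `[0, 1]`.
#' @export
mean_clustering <- function(adj) {
  mean(local_clustering(adj))
}

local_clustering <- function(adj) {
  g <- as_igraph(adj)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0       # degree-1 nodes
  cc
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs with a finite
#' path; pairs in different components are excluded.  A graph with no
#' edges has no finite pair and yields `NA` with a warning.
#'
#' @inheritParams node_degrees
#' @return Mean shortest path length (>= 1 when any edge exists).
#' @export
characteristic_path_length <- function(adj) {
  g <- as_igraph(adj)
  if (igraph::ecount(g) == 0L) {
    warning("graph has no edges: characteristic path length undefined")
    return(NA_real_)
  }
  igraph::mean_distance(g, unconnected = TRUE)
}

nodal_path_length <- function(adj) {
  g <- as_igraph(adj)
  d <- igraph::distances(g)
  diag(d) <- Inf
  apply(d, 1L, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin)) mean(fin) else NA_real_
  })
}

#' Degree-preserving randomisation
#'
#' Rewires the graph by repeated double-edge swaps that reject self-loops
#' and multi-edges, producing a random reference network with exactly the
#' input's degree sequence.  A complete graph admits no legal swap and is
#' returned unchanged.
#'
#' @inheritParams node_degrees
#' @param n_swap_per_edge Attempted swaps per edge (default 10, a standard
#'   mixing heuristic).
#' @param seed Integer seed; the result is deterministic given it.
#' @return A 0/1 adjacency matrix with the same degree sequence.
#' @export
degree_preserving_randomize <- function(adj, n_swap_per_edge = 10L, seed = 1L) {
  adj <- as_adj_matrix(adj)
  g <- as_igraph(adj)
  m <- igraph::ecount(g)
  if (m < 2L) stop("need at least 2 edges to rewire", call. = FALSE)
  rg <- with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(niter = n_swap_per_edge * m)))
  out <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(adj)
  out
}

#' Small-world normalisation
#'
#' Divides the network's mean clustering coefficient and characteristic
#' path length by the corresponding means over `n_reference` randomised
#' reference networks of identical size and degree distribution, yielding
#' gamma (normalised clustering) and lambda (normalised path length).
#' Their ratio sigma = gamma/lambda is the small-world coefficient: values
#' well above 1 indicate clustered-yet-integrated topology, decline toward
#' 1 indicates randomisation of the network.
#'
#' @inheritParams node_degrees
#' @param n_reference Number of reference networks (default 5).
#' @param seed Master seed; each reference uses a seed derived from it.
#' @return List with `gamma`, `lambda`, `sigma`, `clustering`,
#'   `path_length`, `ref_clustering`, `ref_path_length`.
#' @export
normalized_small_world <- function(adj, n_reference = 5L, seed = 1L) {
  adj <- as_adj_matrix(adj)
  if (n_reference < 1L) stop("'n_reference' must be >= 1", call. = FALSE)
  C <- mean_clustering(adj)
  L <- characteristic_path_length(adj)
  ref_C <- numeric(n_reference)
  ref_L <- numeric(n_reference)
  for (i in seq_len(n_reference)) {
    r <- degree_preserving_randomize(adj, seed = seed + i - 1L)
    ref_C[i] <- mean_clustering(r)
    ref_L[i] <- characteristic_path_length(r)
  }
  gamma <- C / mean(ref_C)
  lambda <- L / mean(ref_L)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       clustering = C, path_length = L,
       ref_clustering = ref_C, ref_path_length = ref_L)
}

#' Global network measures
#'
#' Aggregates size (node count), mean node degree, total edge count,
#' connectivity density, mean clustering, characteristic path length, and
#' the small-world normalisation gamma, lambda, sigma.
#'
#' @inheritParams normalized_small_world
#' @return `gmnet_global_metrics` list; `sigma = gamma/lambda` exactly.
#' @export
compute_global_metrics <- function(adj, n_reference = 5L, seed = 1L) {
  adj <- as_adj_matrix(adj)
  n <- nrow(adj)
  deg <- node_degrees(adj)
  e <- sum(deg) / 2
  sw <- normalized_small_world(adj, n_reference = n_reference, seed = seed)
  structure(list(
    size = n,
    degree = mean(deg),
    n_edges = e,
    density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    clustering = sw$clustering,
    path_length = sw$path_length,
    gamma = sw$gamma,
    lambda = sw$lambda,
    sigma = sw$sigma,
    n_reference = as.integer(n_reference),
    reference_seed = as.integer(seed)
  ), class = "gmnet_global_metrics")
}

#' @export
print.gmnet_global_metrics <- function(x, ...) {
  cat("Global network measures\n")
  cat(sprintf("  size        %d nodes\n", x$size))
  cat(sprintf("  degree      %.2f (mean; %d edges)\n", x$degree, x$n_edges))
  cat(sprintf("  density     %.4f\n", x$density))
  cat(sprintf("  clustering  %.4f    path length %.4f\n",
              x$clustering, x$path_length))
  cat(sprintf("  gamma %.3f  lambda %.3f  sigma %.3f  (%d reference networks)\n",
              x$gamma, x$lambda, x$sigma, x$n_reference))
  invisible(x)
}

#' Regional network measures
#'
#' Averages the nodal measures (degree, clustering coefficient, nodal path
#' length — the mean finite distance from the node to all others) and the
#' nodal grey-matter volume over the nodes labelled with each atlas region.
#' Regions present in `regions` but holding no nodes get `NA` rows.
#'
#' @inheritParams node_degrees
#' @param node_labels Integer atlas label per node (0/NA = unlabelled).
#' @param node_volumes Grey-matter volume per node.
#' @param regions Optional integer vector of regions to report (defaults
#'   to the labels present).
#' @return Data frame with one row per region: `region`, `n_nodes`,
#'   `degree`, `clustering`, `path_length`, `gm_volume`.
#' @export
compute_regional_metrics <- function(adj, node_labels, node_volumes = NULL,
                                     regions = NULL) {
  adj <- as_adj_matrix(adj)
  n <- nrow(adj)
  if (length(node_labels) != n)
    stop("'node_labels' must have one entry per node", call. = FALSE)
  if (is.null(node_volumes)) node_volumes <- rep(NA_real_, n)
  deg <- node_degrees(adj)
  cc <- local_clustering(adj)
  pl <- nodal_path_length(adj)
  lab <- as.integer(node_labels)
  if (is.null(regions))
    regions <- sort(unique(lab[!is.na(lab) & lab > 0]))
  rows <- lapply(regions, function(r) {
    idx <- which(!is.na(lab) & lab == r)
    if (!length(idx))
      return(data.frame(region = r, n_nodes = 0L, degree = NA_real_,
                        clustering = NA_real_, path_length = NA_real_,
                        gm_volume = NA_real_))
    data.frame(region = r, n_nodes = length(idx),
               degree = mean(deg[idx]),
               clustering = mean(cc[idx]),
               path_length = mean(pl[idx]),
               gm_volume = mean(node_volumes[idx]))
  })
  do.call(rbind, rows)
}
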