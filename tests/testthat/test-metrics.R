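test_that("trivial graphs give textbook values", {
  k5 <- complete_graph(5)
  expect_equal(node_degrees(k5), rep(4L, 5))
  expect_equal(mean_clustering(k5), 1)
  expect_equal(characteristic_path_length(k5), 1)

  st <- star_graph(5)
  expect_equal(mean_clustering(st), 0)       # no triangles
  expect_equal(node_degrees(st), c(5L, rep(1L, 5)))

  p3 <- path_graph(3)
  expect_equal(characteristic_path_length(p3), 4 / 3)  # distances 1,1,2

  tri <- complete_graph(3)
  expect_equal(mean_clustering(tri), 1)

  empty <- matrix(0L, 4, 4)
  expect_equal(node_degrees(empty), rep(0L, 4))
  expect_warning(L <- characteristic_path_length(empty), "no edges")
  expect_true(is.na(L))
})

test_that("degrees, clustering, path length match brute-force oracles", {
  graphs <- list(
    complete_graph(10), star_graph(8), path_graph(12), ring_lattice(30, 4),
    er_graph(60, 0.2, seed = 101), er_graph(100, 0.1, seed = 102),
    er_graph(200, 0.05, seed = 103))
  for (adj in graphs) {
    expect_identical(node_degrees(adj), bf_degrees(adj))
    expect_equal(mean_clustering(adj), bf_mean_clustering(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0)
      expect_equal(characteristic_path_length(adj), bf_path_length(adj),
                   tolerance = 1e-12)
  }
})

test_that("clustering on a seeded ER graph equals triple-loop triangle enumeration", {
  adj <- er_graph(60, 0.2, seed = 55)
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    tri <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b] == 1) tri <- tri + 1
    cc[i] <- tri / choose(length(nb), 2)
  }
  expect_equal(mean_clustering(adj), mean(cc), tolerance = 1e-12)
})

test_that("degree-preserving rewiring keeps the degree sequence exactly", {
  for (adj in list(er_graph(50, 0.15, seed = 31), ring_lattice(40, 6),
                   ws_graph(60, 6, 0.1, seed = 32))) {
    r <- degree_preserving_randomize(adj, seed = 5)
    expect_identical(sort(bf_degrees(r)), sort(bf_degrees(adj)))
    expect_identical(bf_degrees(r), bf_degrees(adj))  # per node, not just sorted
    expect_true(all(diag(r) == 0))
    expect_identical(r, t(r))
  }
  # complete graph admits no legal swap
  k8 <- complete_graph(8)
  expect_identical(degree_preserving_randomize(k8, seed = 1), k8)
  # determinism
  adj <- er_graph(40, 0.2, seed = 77)
  expect_identical(degree_preserving_randomize(adj, seed = 9),
                   degree_preserving_randomize(adj, seed = 9))
  expect_error(degree_preserving_randomize(matrix(0L, 5, 5)), "2 edges")
})

test_that("small-world normalisation: sigma identity and random-graph null", {
  adj <- er_graph(300, 0.05, seed = 41)
  sw <- normalized_small_world(adj, n_reference = 5, seed = 2)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
  # an ER graph is (approximately) its own degree-matched null
  expect_equal(sw$gamma, 1, tolerance = 0.15)
  expect_equal(sw$lambda, 1, tolerance = 0.05)
})

test_that("global metrics aggregate consistently", {
  k10 <- complete_graph(10)
  g <- compute_global_metrics(k10, n_reference = 2, seed = 1)
  expect_identical(g$size, 10L)
  expect_equal(g$degree, 9)
  expect_equal(g$density, 1)
  expect_equal(g$clustering, 1)
  expect_equal(g$path_length, 1)
  expect_identical(g$sigma, g$gamma / g$lambda)

  adj <- er_graph(80, 0.1, seed = 91)
  g2 <- compute_global_metrics(adj, n_reference = 2, seed = 1)
  expect_equal(g2$n_edges, sum(adj) / 2)
  expect_equal(g2$density, sum(adj) / (80 * 79))
  expect_identical(g2$sigma, g2$gamma / g2$lambda)
})

test_that("regional metrics equal an independent group-by computation", {
  adj <- er_graph(60, 0.15, seed = 71)
  labels <- rep(c(1L, 2L), each = 30)
  vols <- runif(60, 5, 20)
  reg <- compute_regional_metrics(adj, labels, vols)
  deg <- bf_degrees(adj)
  cc <- bf_local_clustering(adj)
  d <- bf_distances(adj); diag(d) <- Inf
  npl <- apply(d, 1, function(r) mean(r[is.finite(r)]))
  for (r in 1:2) {
    idx <- which(labels == r)
    row <- reg[reg$region == r, ]
    expect_identical(row$n_nodes, length(idx))
    expect_equal(row$degree, mean(deg[idx]), tolerance = 1e-12)
    expect_equal(row$clustering, mean(cc[idx]), tolerance = 1e-12)
    expect_equal(row$path_length, mean(npl[idx]), tolerance = 1e-12)
    expect_equal(row$gm_volume, mean(vols[idx]), tolerance = 1e-12)
  }
  expect_equal(sum(reg$n_nodes), nrow(adj))  # regions partition the nodes
})

test_that("single-region labelling reduces to global nodal means; empty regions are NA", {
  adj <- er_graph(25, 0.3, seed = 81)
  reg <- compute_regional_metrics(adj, rep(1L, 25), rep(1, 25),
                                  regions = c(1L, 2L))
  expect_equal(reg$degree[1], mean(node_degrees(adj)))
  expect_equal(reg$clustering[1], mean_clustering(adj), tolerance = 1e-12)
  expect_identical(reg$n_nodes[2], 0L)
  expect_true(is.na(reg$degree[2]))     # missing, not zero
})
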