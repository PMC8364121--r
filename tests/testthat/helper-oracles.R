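# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive (loops, enumeration) and share no code with the
# package internals they check.

# Erdos-Renyi adjacency matrix
er_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L; adj
}

star_graph <- function(n_leaves) {
  adj <- matrix(0L, n_leaves + 1, n_leaves + 1)
  adj[1, -1] <- adj[-1, 1] <- 1L
  adj
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}

# ring lattice: each node connected to k/2 neighbours on each side
ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k %/% 2)) {
    j <- ((i - 1 + s) %% n) + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

# Watts-Strogatz: ring lattice with random rewiring
ws_graph <- function(n, k, p, seed) {
  set.seed(seed)
  adj <- ring_lattice(n, k)
  for (i in seq_len(n)) for (s in seq_len(k %/% 2)) {
    j <- ((i - 1 + s) %% n) + 1
    if (runif(1) < p) {
      candidates <- which(adj[i, ] == 0L)
      candidates <- setdiff(candidates, i)
      if (length(candidates)) {
        newj <- candidates[sample.int(length(candidates), 1)]
        adj[i, j] <- adj[j, i] <- 0L
        adj[i, newj] <- adj[newj, i] <- 1L
      }
    }
  }
  adj
}

bf_degrees <- function(adj) {
  n <- nrow(adj)
  out <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    for (j in seq_len(n)) if (j != i && adj[i, j] == 1) d <- d + 1L
    out[i] <- d
  }
  out
}

# triangle-counting clustering by enumeration over neighbour pairs
bf_local_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    tri <- 0L
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] == 1) tri <- tri + 1L
    out[i] <- tri / (k * (k - 1) / 2)
  }
  out
}

bf_mean_clustering <- function(adj) mean(bf_local_clustering(adj))

# all-pairs BFS shortest paths
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (!is.finite(d[s, w])) { d[s, w] <- depth; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bf_path_length <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- Inf
  mean(d[is.finite(d)])
}

# exhaustive rotation-maximised correlation using stats::cor directly
bf_max_rotated_cor <- function(a, b, rotations) {
  best <- -1
  for (j in seq_len(ncol(rotations))) {
    r <- suppressWarnings(cor(a, b[rotations[, j]]))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

# Benjamini-Hochberg step-up written out longhand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# tiny structured image: two texture families so some cube pairs correlate
structured_image <- function(shape, seed, noise = 0.3) {
  set.seed(seed)
  atlas <- gmnet::synthetic_atlas(shape, max(1L, shape[3] %/% 3L %/% 2L))
  protos <- matrix(rnorm(27 * 2), 27)
  gmnet::simulate_subject_image(shape, atlas, protos,
                                rep_len(1:2, max(atlas)),
                                degradation = 0.4, noise_sd = noise)
}
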