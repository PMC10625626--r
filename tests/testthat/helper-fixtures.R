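# shared fixture builders and independent oracles

make_intensity <- function(values, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep(c("control", "knockout"), each = ncol(values) / 2),
                              colnames(values))
  }
  intensity_matrix(values, groups = groups)
}

# random intensity matrix, no planted structure
random_intensity <- function(n_features = 50, n_per_group = 3, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(2^rnorm(n_features * 2 * n_per_group, 20, 2),
                nrow = n_features,
                dimnames = list(sprintf("p%03d", seq_len(n_features)),
                                c(sprintf("c%d", seq_len(n_per_group)),
                                  sprintf("k%d", seq_len(n_per_group)))))
    make_intensity(v)
  })
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix —
# independent of igraph's BFS
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# brute-force GSEA enrichment score: recompute the deviation at every prefix
# from scratch (O(N^2)); same tie convention (positive wins an exact tie)
brute_force_es <- function(scores, hit, weight) {
  N <- length(scores); K <- sum(hit)
  w <- abs(scores)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  total_w <- sum(w)
  dev <- numeric(N)
  for (i in seq_len(N)) {
    idx <- seq_len(i)
    dev[i] <- sum(w[idx][hit[idx]]) / total_w - sum(!hit[idx]) / (N - K)
  }
  mx <- max(dev); mn <- min(dev)
  if (mx + mn >= -1e-12) mx else mn
}

# hypergeometric upper tail by direct summation
hyper_upper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# random undirected graph as igraph + adjacency, for distance oracles
random_graph <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    adj <- matrix(0L, n_nodes, n_nodes)
    adj[upper.tri(adj)] <- as.integer(runif(n_nodes * (n_nodes - 1) / 2) < p_edge)
    adj <- adj + t(adj)
    dimnames(adj) <- list(sprintf("n%02d", 1:n_nodes), sprintf("n%02d", 1:n_nodes))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    list(graph = g, adj = adj)
  })
}
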