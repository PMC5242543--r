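# Fixtures and independent oracles used across the suite.

# symmetric dissimilarity matrix with uniform entries and zero diagonal
rand_dissimilarity <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d + t(d)
}

# brute-force beta0 at threshold lam: breadth-first component count on the
# graph with edges {d_ij < lam}, via igraph (independent of the union-find
# implementation under test)
bfs_beta0 <- function(d, lam) {
  adj <- (d < lam) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

# all-pairs shortest-path hop diameter by Floyd-Warshall
fw_diameter <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  dist[adj != 0] <- 1
  diag(dist) <- 0
  for (k in seq_len(n)) {
    dist <- pmin(dist, outer(dist[, k], dist[k, ], "+"))
  }
  max(dist[is.finite(dist)])
}

# path graph 1-2-...-n as a connectivity_matrix
path_graph_cm <- function(n) {
  vals <- matrix(0, n, n)
  for (i in seq_len(n - 1)) vals[i, i + 1] <- vals[i + 1, i] <- 1
  connectivity_matrix(vals, weighted = FALSE)
}

cm <- function(vals, ...) connectivity_matrix(as.matrix(vals), ...)

# write a matrix to a temp file in a given delimiter, return the path
write_temp_matrix <- function(vals, delimiter = ",") {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  lines <- apply(vals, 1, paste, collapse = delimiter)
  writeLines(lines, path)
  path
}

# standard small forward-model pair used by several tests
toy_pair <- function(n = 40, coefs = c(-0.3, 0.05, 0.01),
                     g = 0.01, noise_sd = 0, seed = 42) {
  s <- generate_modular_sc(n, 4, 0.6, 0.1, seed = seed)
  f <- forward_model(s, coefs, global_input = g, noise_sd = noise_sd,
                     seed = seed + 1)
  list(s = s, f = f)
}
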