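# Independent oracles and small fixture builders shared across tests.

# Enumerate all set partitions of n items (restricted growth strings);
# feasible for n <= 8 (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force maximum modularity by exhaustive search over all partitions.
brute_force_q <- function(m) {
  max(vapply(all_partitions(nrow(m)), function(p) modularity_value(m, p),
             numeric(1)))
}

# Component count of the graph retaining the top-k edges, via igraph's
# breadth-first component search (independent of the union-find path).
bfs_components_topk <- function(m, k) {
  n <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  o <- order(-w, idx[, 1L], idx[, 2L])
  el <- idx[o, , drop = FALSE][seq_len(k), , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$no
}

# Random symmetric Fisher-z-like matrix from a short noise time series.
random_z_matrix <- function(n_nodes, seed, len = 3 * n_nodes) {
  set.seed(seed)
  correlation_matrix(matrix(rnorm(n_nodes * len), nrow = n_nodes))
}

# Small cohort configuration used where full scale is not the point.
small_config <- function(seed = 1L, ...) {
  sim_config(n_participants = 24L, n_nodes = 20L, n_networks = 4L,
             series_length = 80L, domains = "fluid", seed = seed, ...)
}

# Null cohort: no programmed age, topology or NART effects on behavior.
null_config <- function(seed = 1L, ...) {
  sim_config(n_participants = 60L, n_nodes = 30L, n_networks = 5L,
             series_length = 120L, domains = "fluid",
             seg_decline_slope = 0, beta_age_behavior = 0,
             beta_auc_behavior = 0, beta_nart_behavior = 0,
             seed = seed, ...)
}
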