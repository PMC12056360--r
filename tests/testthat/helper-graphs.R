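# Graph fixtures and independent oracles used across test files.

adj_from_edges <- function(n, edges, labels = NULL) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  }
  if (!is.null(labels)) dimnames(a) <- list(labels, labels)
  a
}

path_graph <- function(n) adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}
star_graph <- function(n) adj_from_edges(n, lapply(2:n, function(i) c(1, i)))

random_adjacency <- function(n, p_edge = 0.5) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

# independent reference values through igraph
igraph_metrics <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  n <- nrow(a)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  ge <- rowSums(inv) / (n - 1)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  bc <- igraph::betweenness(g) / ((n - 1) * (n - 2) / 2)
  list(ge = unname(ge), cc = unname(cc), bc = unname(bc))
}

# brute-force betweenness: enumerate every shortest path explicitly
brute_force_bc <- function(a) {
  n <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  score <- numeric(n)
  enum_paths <- function(cur, target, dist_left) {
    if (cur == target) return(list(cur))
    out <- list()
    for (nb in which(a[cur, ] == 1)) {
      if (is.finite(d[nb, target]) && d[nb, target] == dist_left - 1) {
        for (p in enum_paths(nb, target, dist_left - 1)) {
          out[[length(out) + 1]] <- c(cur, p)
        }
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- enum_paths(s, t, d[s, t])
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        score[interior] <- score[interior] + 1 / length(paths)
      }
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

# tiny cohort used by several files
small_cohort <- function(seed = 42, n_subjects = 10, planted = NULL,
                         noise_sd = 1, ...) {
  cfg <- sim_config(n_subjects = n_subjects, roi_set = roi_set("cortical_SMN"),
                    n_timepoints = 80, planted_edges = planted,
                    noise_sd = noise_sd, seed = seed, ...)
  simulate_cohort(cfg)
}
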