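#' Binarize a weight matrix at a threshold
#'
#' Edges are the strictly supra-threshold entries (`weight > tau`); the
#' diagonal is always zero. Thresholds are applied to the Pearson r matrix,
#' so negative correlations never create edges on the usual 0.15-0.50 grid.
#'
#' @param w Symmetric weight matrix (typically Pearson r).
#' @param tau Threshold.
#' @return Binary adjacency matrix of the same dimension.
#' @export
binarize <- function(w, tau) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  a <- (w > tau) & !is.na(w)
  a <- a & t(a)
  diag(a) <- FALSE
  storage.mode(a) <- "integer"
  dimnames(a) <- dimnames(w)
  a
}

#' Unweighted shortest-path lengths (hop counts)
#'
#' Breadth-first search from every node; `Inf` marks pairs in different
#' components and the diagonal is 0.
#'
#' @param a Binary adjacency matrix.
#' @return Symmetric matrix of hop counts.
#' @export
shortest_path_lengths <- function(a) {
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] != 0))
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Nodal global efficiency
#'
#' Mean inverse shortest-path length from a node to every other node, with
#' `1/Inf = 0` for unreachable nodes: `GE(i) = mean_{j != i} 1/d(i, j)`.
#'
#' @param a Binary adjacency matrix (`n >= 2`).
#' @param node Optional node index or label; default all nodes.
#' @return Named numeric vector of efficiencies in `[0, 1]`.
#' @export
global_efficiency_node <- function(a, node = NULL) {
  n <- nrow(a)
  stopifnot(n >= 2)
  d <- shortest_path_lengths(a)
  inv <- 1 / d
  diag(inv) <- 0
  ge <- rowSums(inv) / (n - 1)
  if (is.null(node)) ge else ge[node]
}

#' Nodal clustering coefficient
#'
#' Fraction of possible edges among a node's neighbours that are present:
#' `CC(i) = 2 e_i / (k_i (k_i - 1))`, defined as 0 for degree < 2.
#'
#' @inheritParams global_efficiency_node
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient_node <- function(a, node = NULL) {
  n <- nrow(a)
  k <- rowSums(a)
  cc <- numeric(n)
  names(cc) <- rownames(a)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(a[i, ] != 0)
    e_i <- sum(a[nb, nb]) / 2
    cc[i] <- 2 * e_i / (k[i] * (k[i] - 1))
  }
  if (is.null(node)) cc else cc[node]
}

#' Nodal betweenness centrality
#'
#' Proportion of shortest paths between other node pairs that pass through
#' the node, with fractional counting over tied shortest paths and
#' disconnected pairs skipped, normalised by the `(n-1)(n-2)/2` unordered
#' pairs so the value lies in `[0, 1]`. Computed by breadth-first
#' shortest-path counting with dependency accumulation (Brandes' method).
#'
#' @inheritParams global_efficiency_node
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality_node <- function(a, node = NULL) {
  n <- nrow(a)
  stopifnot(n >= 3)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] != 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (w in nbrs[[v]]) {
        if (dist[w] == dist[v] + 1L) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  # each unordered pair contributed twice (once per endpoint as source)
  bc <- bc / 2 / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(a)
  if (is.null(node)) bc else bc[node]
}

#' Default graph threshold grid
#'
#' The 36-point grid 0.15 to 0.50 in steps of 0.01 over which adjacency
#' matrices and nodal metrics are computed; below 0.15 the graphs become too
#' sparse to be informative, above 0.5 too few edges survive.
#'
#' @param tau_min,tau_max,tau_step Grid parameters.
#' @return Numeric vector of thresholds.
#' @export
default_threshold_grid <- function(tau_min = 0.15, tau_max = 0.50,
                                   tau_step = 0.01) {
  stopifnot(tau_min < tau_max, tau_step > 0)
  seq(tau_min, tau_max, by = tau_step)
}

#' Nodal graph metrics over a threshold sweep
#'
#' Binarizes the weight matrix at every grid threshold and computes nodal
#' global efficiency (GE), clustering coefficient (CC) and betweenness
#' centrality (BC) at each, producing the metric-versus-threshold curves
#' that [auc_graph_metrics()] summarises.
#'
#' @param w Symmetric weight matrix (Pearson r).
#' @param grid Threshold grid, default [default_threshold_grid()].
#' @return Tibble of class `fc_sweep` with columns `tau`, `node`, `metric`
#'   (`"GE"`, `"CC"`, `"BC"`) and `value`.
#' @export
metric_threshold_sweep <- function(w, grid = default_threshold_grid()) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), nrow(w) >= 3,
            !is.unsorted(grid, strictly = TRUE))
  labs <- rownames(w)
  if (is.null(labs)) labs <- paste0("node", seq_len(nrow(w)))
  out <- purrr::map_dfr(grid, function(tau) {
    a <- binarize(w, tau)
    tibble::tibble(
      tau = tau,
      node = rep(labs, 3L),
      metric = rep(c("GE", "CC", "BC"), each = length(labs)),
      value = c(global_efficiency_node(a),
                clustering_coefficient_node(a),
                betweenness_centrality_node(a))
    )
  })
  class(out) <- c("fc_sweep", class(out))
  out
}

#' Area under the metric-versus-threshold curve
#'
#' Trapezoidal integral of each node x metric curve over the threshold
#' grid, yielding a threshold-free scalar per node and metric (the feature
#' the elastic-net stage consumes). A constant curve `c` over
#' `[0.15, 0.5]` integrates to `0.35 c`.
#'
#' @param sweep An `fc_sweep` from [metric_threshold_sweep()].
#' @return Tibble with columns `node`, `metric`, `auc`.
#' @export
auc_graph_metrics <- function(sweep) {
  stopifnot(all(c("tau", "node", "metric", "value") %in% names(sweep)))
  dplyr::summarise(
    dplyr::group_by(sweep, .data$node, .data$metric),
    auc = trapezoid_auc(.data$tau, .data$value),
    .groups = "drop"
  )
}

#' Trapezoidal quadrature
#' @param x Strictly increasing abscissae (>= 2 points).
#' @param y Ordinates.
#' @return The trapezoidal integral.
#' @export
trapezoid_auc <- function(x, y) {
  stopifnot(length(x) >= 2L, length(x) == length(y))
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Per-subject graph-metric AUC features for a cohort
#'
#' Runs the threshold sweep on every subject's correlation matrix and
#' returns the AUC of each nodal metric — the subjects x (ROI, metric)
#' feature table used by [stability_selection()].
#'
#' @param edges An `fc_edge_table` from [connectivity_matrices()].
#' @param grid Threshold grid.
#' @return Tibble with columns `subject`, `node`, `metric`, `auc`.
#' @export
graph_metric_auc <- function(edges, grid = default_threshold_grid()) {
  purrr::map_dfr(unique(edges$subject), function(s) {
    w <- edge_table_matrix(edges, s, "r")
    dplyr::mutate(auc_graph_metrics(metric_threshold_sweep(w, grid)),
                  subject = s, .before = 1)
  })
}
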