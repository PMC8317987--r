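#' Default proportional-density grid
#'
#' Densities from 15% to 30% of all possible edges in steps of 2.5%,
#' the grid over which binary graph metrics are averaged.
#'
#' @return Numeric vector of 7 densities.
#' @export
default_density_grid <- function() seq(0.150, 0.300, by = 0.025)

#' Threshold a connectivity matrix at a target edge density
#'
#' Retains exactly `k = round(density * N(N-1)/2)` strongest
#' off-diagonal edges (half-up rounding) by signed Fisher-z weight,
#' most-positive first. Ties at the cutoff are broken by ascending
#' `(i, j)` lexicographic edge index so thresholding is deterministic
#' across platforms.
#'
#' @param fc An [compute_fc()] matrix (any symmetric numeric matrix with
#'   ignorable diagonal works).
#' @param density Target fraction of possible edges, in (0, 1].
#'
#' @return A `binary_graph`: list with `adjacency` (symmetric 0/1
#'   matrix, zero diagonal) and `density`.
#' @export
threshold_by_density <- function(fc, density) {
  if (length(density) != 1 || density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]", call. = FALSE)
  }
  n <- nrow(fc)
  ij <- which(upper.tri(fc), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]  # (i, j) lexicographic
  w <- fc[ij]
  e_max <- nrow(ij)
  k <- round_half_up(density * e_max)
  if (k == 0) {
    stop("density ", density, " retains zero edges (degenerate)", call. = FALSE)
  }
  keep <- order(-w, seq_len(e_max))[seq_len(k)]
  adj <- matrix(0L, n, n, dimnames = dimnames(fc))
  adj[ij[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = density), class = "binary_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Local graph metrics on a binary graph
#'
#' Four per-node metrics of a binary undirected graph:
#' * `degree_centrality()` — number of incident edges.
#' * `clustering_coefficient()` — fraction of a node's neighbor pairs
#'   that are connected; 0 for degree < 2.
#' * `betweenness_centrality()` — unnormalized shortest-path
#'   betweenness with each unordered pair counted once; pairs with no
#'   connecting path contribute 0.
#' * `local_efficiency()` — global efficiency (mean inverse shortest
#'   path length, unreachable pairs contributing 0) of the subgraph
#'   induced on the node's neighbors; 0 for degree < 2.
#'
#' @param g A `binary_graph` from [threshold_by_density()], or a bare
#'   symmetric 0/1 adjacency matrix.
#'
#' @return Named numeric vector, one value per node.
#' @name graph_metrics
NULL

as_binary_graph <- function(g) {
  if (inherits(g, "binary_graph")) return(g)
  if (is.matrix(g)) return(structure(list(adjacency = g, density = NA_real_),
                                     class = "binary_graph"))
  stop("expected a binary_graph or adjacency matrix", call. = FALSE)
}

#' @rdname graph_metrics
#' @export
degree_centrality <- function(g) {
  g <- as_binary_graph(g)
  rowSums(g$adjacency)
}

#' @rdname graph_metrics
#' @export
clustering_coefficient <- function(g) {
  g <- as_binary_graph(g)
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  names(cc) <- rownames(g$adjacency) %||% seq_len(nrow(g$adjacency))
  cc
}

#' @rdname graph_metrics
#' @export
betweenness_centrality <- function(g) {
  g <- as_binary_graph(g)
  bc <- igraph::betweenness(as_igraph(g), directed = FALSE, normalized = FALSE)
  if (is.null(names(bc))) names(bc) <- seq_len(nrow(g$adjacency))
  bc
}

# All-pairs shortest-path distances of a small binary graph by
# level-synchronous BFS on the adjacency matrix (one BLAS product per
# level). Unreachable pairs stay Inf.
adjacency_distances <- function(adj) {
  k <- nrow(adj)
  d <- matrix(Inf, k, k)
  diag(d) <- 0
  d[adj > 0] <- 1
  reach <- adj > 0
  diag(reach) <- TRUE
  t <- 1
  repeat {
    nreach <- ((reach %*% adj) > 0) | reach
    newly <- nreach & !reach
    if (!any(newly)) break
    t <- t + 1
    d[newly] <- t
    reach <- nreach
    if (t > k) break
  }
  d
}

#' @rdname graph_metrics
#' @export
local_efficiency <- function(g) {
  g <- as_binary_graph(g)
  adj <- g$adjacency
  n <- nrow(adj)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    # efficiency of the subgraph induced on the neighbors of i
    d <- adjacency_distances(adj[nb, nb, drop = FALSE])
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0 # unreachable neighbor pairs contribute 0
    le[i] <- mean(inv)
  }
  names(le) <- rownames(adj) %||% seq_len(n)
  le
}

metric_funs <- list(
  DC = degree_centrality,
  CC = clustering_coefficient,
  BC = betweenness_centrality,
  LE = local_efficiency
)

#' Density-averaged node metrics for one connectivity matrix
#'
#' Thresholds and binarizes the matrix at every density of the grid,
#' computes the four local metrics per binary graph, and averages each
#' metric per node across densities.
#'
#' @param fc An [compute_fc()] matrix.
#' @param densities Density grid, default [default_density_grid()].
#' @param metrics Metric subset, any of `"DC"`, `"CC"`, `"BC"`, `"LE"`.
#'
#' @return Long tibble with columns `node_id`, `metric`, `value`.
#' @export
metrics_across_densities <- function(fc, densities = default_density_grid(),
                                     metrics = c("DC", "CC", "BC", "LE")) {
  if (length(densities) == 0 || any(diff(densities) <= 0) ||
      any(densities <= 0 | densities > 1)) {
    stop("densities must be strictly increasing values in (0, 1]", call. = FALSE)
  }
  metrics <- match.arg(metrics, names(metric_funs), several.ok = TRUE)
  node_ids <- attr(fc, "node_ids") %||% rownames(fc) %||% as.character(seq_len(nrow(fc)))
  acc <- matrix(0, nrow(fc), length(metrics),
                dimnames = list(node_ids, metrics))
  for (d in densities) {
    g <- threshold_by_density(fc, d)
    for (m in metrics) acc[, m] <- acc[, m] + metric_funs[[m]](g)
  }
  acc <- acc / length(densities)
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(acc), node_id = node_ids, .before = 1),
    -"node_id", names_to = "metric", values_to = "value"
  )
}

#' Density-averaged node metrics for every subject
#'
#' @param fc_tbl Tibble from [cohort_fc()] (columns `subject_id`,
#'   optionally `group`, and list-column `fc`).
#' @inheritParams metrics_across_densities
#'
#' @return Long tibble: `subject_id`, `node_id`, `metric`, `value` —
#'   one row per (subject, node, metric).
#' @export
compute_node_metrics <- function(fc_tbl, densities = default_density_grid(),
                                 metrics = c("DC", "CC", "BC", "LE")) {
  stopifnot(is.data.frame(fc_tbl), all(c("subject_id", "fc") %in% names(fc_tbl)))
  purrr::map2_dfr(fc_tbl$fc, fc_tbl$subject_id, function(fc, sid) {
    dplyr::mutate(metrics_across_densities(fc, densities, metrics),
                  subject_id = sid, .before = 1)
  })
}
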