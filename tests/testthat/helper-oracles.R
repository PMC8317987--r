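# Independent brute-force graph oracles: Floyd-Warshall distances and
# dynamic-programming shortest-path counts, deliberately distinct from
# the package's igraph-backed implementations.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# sigma[s, t] = number of distinct shortest s-t paths
bf_path_counts <- function(adj, d = bf_distances(adj)) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      if (d[s, t] == 1) {
        sigma[s, t] <- 1
      } else {
        pred <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  sigma
}

bf_dc <- function(adj) rowSums(adj)

bf_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) t_i <- t_i + adj[nb[a], nb[b]]
    }
    2 * t_i / (k * (k - 1))
  }, numeric(1))
}

bf_bc <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc
}

bf_le <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    d <- bf_distances(adj[nb, nb, drop = FALSE])
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    mean(inv) # unordered pairs; equals ordered-pair mean by symmetry
  }, numeric(1))
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  adj
}

# Direct step-up implementation of the Benjamini-Hochberg adjustment,
# independent of stats::p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small toy feature table: n subjects, one informative feature
# (group-shifted by delta) plus pure-noise features.
toy_feature_table <- function(n_per_group = 20, n_noise = 10, delta = 2,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("HC", "LBP"), each = n_per_group)
  x <- matrix(rnorm(n * (n_noise + 1)), n)
  x[, 1] <- x[, 1] + ifelse(group == "HC", delta / 2, -delta / 2)
  colnames(x) <- c("DC_signal", paste0("DC_noise", seq_len(n_noise)))
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)),
                 group = group) |>
    dplyr::bind_cols(tibble::as_tibble(x))
}

# Sparse-effect benchmark table: n_signal group-shifted features among
# many pure-noise ones (the regime where subset pruning should help).
sparse_feature_table <- function(n_per_group = 30, n_signal = 10,
                                 n_noise = 500, delta = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("HC", "LBP"), each = n_per_group)
  x <- matrix(rnorm(n * (n_signal + n_noise)), n)
  x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] +
    ifelse(group == "HC", delta / 2, -delta / 2)
  colnames(x) <- c(paste0("DC_inf", seq_len(n_signal)),
                   paste0("DC_noise", seq_len(n_noise)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), group = group),
    tibble::as_tibble(x)
  )
}

# Small metric-derived feature table from a synthetic cohort.
cohort_feature_table <- function(seed, n_hc = 25, n_lbp = 25, n_nodes = 60,
                                 n_timepoints = 200, n_affected = 8,
                                 effect_size = 2, metrics = "DC",
                                 with_odi = FALSE) {
  cohort <- generate_cohort(cohort_spec(
    n_hc = n_hc, n_lbp = n_lbp, n_nodes = n_nodes,
    n_timepoints = n_timepoints, n_affected = n_affected,
    effect_size = effect_size, noise_sd = 1, seed = seed))
  if (with_odi) cohort <- generate_disability_scores(cohort, seed = seed)
  mt <- compute_node_metrics(cohort_fc(cohort), metrics = metrics)
  list(cohort = cohort, metric_tbl = mt,
       ft = feature_table(mt, cohort$subjects, metrics = metrics))
}
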