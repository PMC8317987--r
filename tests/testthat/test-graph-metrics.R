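fc_from_weights <- function(w, n) {
  # build a symmetric pseudo-FC matrix from an upper-triangular weight
  # vector ordered lexicographically by (i, j)
  m <- matrix(0, n, n)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  m[ij] <- w
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

test_that("thresholding retains round(d * E_max) edges with the tie rule", {
  set.seed(5)
  fc <- fc_from_weights(rnorm(45), 10)
  g <- threshold_by_density(fc, 0.20)
  expect_equal(sum(g$adjacency) / 2, 9) # 0.20 * 45
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))

  # all-equal weights: round(0.15 * 45) = 7 edges, first 7 in (i, j)
  # lexicographic order
  g_tie <- threshold_by_density(fc_from_weights(rep(1, 45), 10), 0.15)
  expect_equal(sum(g_tie$adjacency) / 2, 7)
  expect_equal(which(g_tie$adjacency[1, ] == 1), 2:8)
  expect_equal(sum(g_tie$adjacency[2:10, 2:10]), 0)

  # distinct integer weights 1..45: density 0.20 keeps exactly 37..45
  g_int <- threshold_by_density(fc_from_weights(1:45, 10), 0.20)
  m <- fc_from_weights(1:45, 10)
  kept <- sort(m[upper.tri(m)][g_int$adjacency[upper.tri(m)] == 1])
  expect_equal(kept, 37:45)

  expect_error(threshold_by_density(fc, 0.001), "zero edges")
  expect_error(threshold_by_density(fc, 1.5), "in \\(0, 1\\]")
})

test_that("edge sets are nested and degree monotone across the density grid", {
  set.seed(6)
  fc <- fc_from_weights(rnorm(15 * 14 / 2), 15)
  grid <- default_density_grid()
  adjs <- lapply(grid, function(d) threshold_by_density(fc, d)$adjacency)
  for (i in seq_len(length(grid) - 1)) {
    expect_true(all(adjs[[i]] <= adjs[[i + 1]]))
    expect_true(all(rowSums(adjs[[i]]) <= rowSums(adjs[[i + 1]])))
  }
})

test_that("metrics match hand-derived values on canonical graphs", {
  # triangle
  tri <- adjacency_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(unname(degree_centrality(tri)), rep(2, 3))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  expect_equal(unname(local_efficiency(tri)), rep(1, 3))

  # star with 5 leaves: center degree 5, leaves 1; no triangles
  star5 <- adjacency_from_edges(6, lapply(2:6, function(j) c(1, j)))
  expect_equal(unname(degree_centrality(star5)), c(5, rep(1, 5)))
  expect_equal(unname(clustering_coefficient(star5)), rep(0, 6))
  expect_equal(unname(local_efficiency(star5)), rep(0, 6))
  # star with 4 leaves: center betweenness = C(4,2) = 6
  star4 <- adjacency_from_edges(5, lapply(2:5, function(j) c(1, j)))
  expect_equal(unname(betweenness_centrality(star4)), c(6, rep(0, 4)))

  # path A-B-C
  path3 <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  # empty graph
  expect_equal(unname(degree_centrality(matrix(0L, 4, 4))), rep(0, 4))

  # K4: clustering 1 everywhere
  k4 <- 1 - diag(4)
  expect_equal(unname(clustering_coefficient(k4)), rep(1, 4))

  # square A-B-C-D-A plus diagonal A-C: A and C each sit in 2 triangles
  # over 3 neighbor pairs (value from triangle enumeration), B and D in 1
  # over 1
  sq <- adjacency_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                                     c(1, 3)))
  expect_equal(unname(clustering_coefficient(sq)), bf_cc(sq))
  expect_equal(unname(clustering_coefficient(sq)), c(2/3, 1, 2/3, 1))

  # K4 minus edge C-D: LE(A) = LE(B) = 5/6
  k4m <- adjacency_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                      c(2, 4)))
  expect_equal(unname(local_efficiency(k4m)), c(5/6, 5/6, 1, 1))

  # 5-cycle: all nodes equal by symmetry; the unique 2-step geodesic
  # between a node's neighbors passes through it, so BC = 1 per node
  # (value frozen from the brute-force enumeration oracle)
  ring5 <- adjacency_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                        c(5, 1)))
  expect_equal(unname(betweenness_centrality(ring5)), bf_bc(ring5))
  expect_equal(unname(betweenness_centrality(ring5)), rep(1, 5))
})

test_that("all four metrics agree with brute-force enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.2, 0.7))
    expect_equal(unname(degree_centrality(adj)), bf_dc(adj), tolerance = 1e-9)
    expect_equal(unname(clustering_coefficient(adj)), bf_cc(adj),
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(adj)), bf_bc(adj),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(adj)), bf_le(adj), tolerance = 1e-9)
  }
})

test_that("metric vectors are isomorphism-invariant", {
  set.seed(8)
  adj <- random_adjacency(7, 0.45)
  perm <- sample(7)
  adj_p <- adj[perm, perm]
  for (f in list(degree_centrality, clustering_coefficient,
                 betweenness_centrality, local_efficiency)) {
    expect_equal(unname(f(adj_p)), unname(f(adj))[perm], tolerance = 1e-12)
  }
})

test_that("density averaging matches a naive per-density recomputation", {
  set.seed(9)
  fc <- compute_fc(matrix(rnorm(12 * 60), 12, 60))
  got <- metrics_across_densities(fc)
  grid <- default_density_grid()
  for (m in c("DC", "CC", "BC", "LE")) {
    fn <- switch(m, DC = degree_centrality, CC = clustering_coefficient,
                 BC = betweenness_centrality, LE = local_efficiency)
    manual <- rowMeans(vapply(grid, function(d)
      unname(fn(threshold_by_density(fc, d))), numeric(12)))
    expect_equal(got$value[got$metric == m], manual, tolerance = 1e-12)
  }
  # a single-density grid equals the single-density metrics
  one <- metrics_across_densities(fc, densities = 0.2, metrics = "DC")
  expect_equal(one$value,
               unname(degree_centrality(threshold_by_density(fc, 0.2))))
  # value ranges
  wide <- tidyr::pivot_wider(got, names_from = "metric", values_from = "value")
  expect_true(all(wide$DC >= 0 & wide$DC <= 11))
  expect_true(all(wide$CC >= 0 & wide$CC <= 1))
  expect_true(all(wide$LE >= 0 & wide$LE <= 1))
  expect_true(all(wide$BC >= 0))
})

test_that("compute_node_metrics maps over subjects", {
  set.seed(10)
  subjects <- tibble::tibble(
    subject_id = c("a", "b"),
    group = c("HC", "LBP"),
    series = list(matrix(rnorm(10 * 40), 10, 40),
                  matrix(rnorm(10 * 40), 10, 40))
  )
  mt <- compute_node_metrics(cohort_fc(subjects), densities = c(0.2, 0.3))
  expect_equal(nrow(mt), 2 * 10 * 4)
  expect_setequal(unique(mt$subject_id), c("a", "b"))
  expect_setequal(unique(mt$metric), c("DC", "CC", "BC", "LE"))
})
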