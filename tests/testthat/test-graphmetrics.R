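test_that("weight-to-length inverts positive weights and drops absent edges", {
  W <- matrix(c(0, 1, 2, 0,
                1, 0, 0, 0,
                2, 0, 0, 0.5,
                0, 0, 0.5, 0), 4, 4)
  L <- weight_to_length(W)
  expect_equal(L[1, 2], 1)
  expect_equal(L[1, 3], 0.5)
  expect_equal(L[3, 4], 2)
  expect_true(is.infinite(L[1, 4]))
  expect_equal(diag(L), rep(0, 4))
})

test_that("characteristic path length reproduces worked values", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(characteristic_path_length(K3), 1)
  P3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(characteristic_path_length(P3), 4 / 3, tolerance = 1e-12)
  Tri <- matrix(0, 3, 3)
  Tri[1, 2] <- Tri[2, 1] <- 2; Tri[1, 3] <- Tri[3, 1] <- 2
  Tri[2, 3] <- Tri[3, 2] <- 1
  expect_equal(characteristic_path_length(Tri), 2 / 3, tolerance = 1e-12)
  expect_error(characteristic_path_length(matrix(0, 3, 3)))
  # disconnected: largest component with warning, or Inf on request
  D <- adj_from_edges(4, list(c(1, 2), c(1, 3)))  # node 4 isolated
  expect_warning(l <- characteristic_path_length(D), "disconnected")
  expect_equal(l, 4 / 3, tolerance = 1e-12)
  expect_true(is.infinite(
    characteristic_path_length(D, disconnected = "infinite")))
})

test_that("mean clustering coefficient reproduces worked values", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(mean_clustering_coefficient(K3), 1, tolerance = 1e-12)
  P3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(mean_clustering_coefficient(P3), 0)
  Tri <- matrix(0, 3, 3)
  Tri[1, 2] <- Tri[2, 1] <- 2; Tri[1, 3] <- Tri[3, 1] <- 2
  Tri[2, 3] <- Tri[3, 2] <- 1
  expect_equal(mean_clustering_coefficient(Tri), 0.5^(1 / 3),
               tolerance = 1e-12)
})

test_that("L and C agree with exhaustive oracles on random weighted graphs", {
  for (k in 1:30) {
    n <- 4 + (k %% 5)              # 4..8 nodes
    W <- random_connected_graph(n, density = 0.5, seed = 100 + k)
    expect_equal(characteristic_path_length(W), oracle_char_path_length(W),
                 tolerance = 1e-9)
    expect_equal(mean_clustering_coefficient(W), oracle_clustering(W),
                 tolerance = 1e-9)
  }
})

test_that("null networks preserve the weight multiset and their defining order", {
  W <- random_connected_graph(12, density = 0.4, seed = 7)
  for (kind in c("lattice", "random")) {
    nul <- generate_null(W, kind, seed = 3)
    expect_equal(sort(unclass(nul)[upper.tri(nul) & unclass(nul) > 0]),
                 sort(W[upper.tri(W) & W > 0]), tolerance = 1e-12)
    expect_identical(unclass(generate_null(W, kind, seed = 3)), unclass(nul))
  }
  # lattice nulls cluster at least as strongly as random nulls on average
  set.seed(11)
  cdiff <- vapply(1:20, function(s) {
    W2 <- random_connected_graph(30, density = 0.2, seed = 200 + s)
    mean_clustering_coefficient(generate_null(W2, "lattice", seed = s)) -
      mean_clustering_coefficient(generate_null(W2, "random", seed = s))
  }, numeric(1))
  expect_gt(mean(cdiff), 0)
})

test_that("phi and delta follow the closed-form anchors", {
  expect_equal(swp_from_deltas(0, 0), list(phi = 1, delta = 0))
  a <- swp_from_deltas(0, 1)
  expect_equal(a$phi, 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(a$delta, 1, tolerance = 1e-12)
  b <- swp_from_deltas(1, 0)
  expect_equal(b$delta, -1, tolerance = 1e-12)
  for (d in c(0.2, 0.5, 1)) {
    expect_equal(swp_from_deltas(d, d)$delta, 0, tolerance = 1e-12)
  }
  expect_error(swp_from_deltas(-0.1, 0.5))
})

test_that("small-world propensity separates lattice, small-world, and random", {
  phis <- vapply(1:5, function(s) {
    small_world_propensity(watts_strogatz_weighted(60, 6, 0.1, seed = s),
                           n_null = 5, seed = s * 100)$phi
  }, numeric(1))
  latt <- small_world_propensity(watts_strogatz_weighted(60, 6, 0, seed = 1),
                                 n_null = 5, seed = 100)
  rand <- small_world_propensity(watts_strogatz_weighted(60, 6, 1, seed = 1),
                                 n_null = 5, seed = 100)
  expect_gt(mean(phis), 0.6)
  expect_gt(mean(phis), latt$phi)
  expect_gt(mean(phis), rand$phi)
  # lattice-like: delta_C near 0 and delta near +1; random-like: delta_L near 0
  expect_lt(latt$delta_C, 0.05)
  expect_gt(latt$delta, 0.9)
  expect_lt(rand$delta_L, 0.1)
  expect_lt(rand$delta, -0.8)
  # phi bounded in [0, 1] on arbitrary graphs
  for (s in 1:5) {
    W <- random_connected_graph(15, density = 0.3, seed = 300 + s)
    r <- suppressWarnings(small_world_propensity(W, n_null = 3, seed = s))
    expect_gte(r$phi, 0)
    expect_lte(r$phi, 1)
  }
})
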