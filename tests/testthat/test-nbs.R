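mk_tensors <- function(n_sub, n_nodes, seed, shift_edges = list(),
                       shift = 0) {
  set.seed(seed)
  sym <- function() {
    m <- matrix(rnorm(n_nodes^2), n_nodes)
    (m + t(m)) / 2
  }
  A <- array(0, c(n_sub, n_nodes, n_nodes))
  B <- array(0, c(n_sub, n_nodes, n_nodes))
  for (s in 1:n_sub) { A[s, , ] <- sym(); B[s, , ] <- sym() }
  for (e in shift_edges) {
    A[, e[1], e[2]] <- A[, e[1], e[2]] + shift
    A[, e[2], e[1]] <- A[, e[1], e[2]]
  }
  list(A = A, B = B)
}

test_that("edge-wise paired t matches direct computation and is antisymmetric", {
  tens <- mk_tensors(5, 4, seed = 1)
  expect_true(all(paired_t_matrix(tens$A, tens$A) == 0))
  # hand example: differences 1,2,3 -> t = 2*sqrt(3)
  A <- array(0, c(3, 2, 2)); B <- array(0, c(3, 2, 2))
  A[, 1, 2] <- A[, 2, 1] <- c(1, 2, 3)
  tm <- paired_t_matrix(A, B)
  expect_equal(tm[1, 2], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(paired_t_matrix(B, A)[1, 2], -2 * sqrt(3), tolerance = 1e-12)
  # agreement with stats::t.test edge by edge
  t_pkg <- paired_t_matrix(tens$A, tens$B)
  for (e in list(c(1, 2), c(2, 4), c(3, 4))) {
    t_ref <- stats::t.test(tens$A[, e[1], e[2]], tens$B[, e[1], e[2]],
                           paired = TRUE)$statistic
    expect_equal(t_pkg[e[1], e[2]], unname(t_ref), tolerance = 1e-10)
  }
  # zero-variance differences warn and give t = 0
  A2 <- B2 <- array(0, c(3, 2, 2))
  A2[, 1, 2] <- A2[, 2, 1] <- 1
  expect_warning(tz <- paired_t_matrix(A2, B2), "zero-variance")
  expect_equal(tz[1, 2], 0)
})

test_that("NBS returns no components under the null and bounded p-values", {
  tens <- mk_tensors(8, 5, seed = 2)
  res0 <- nbs_paired(tens$A, tens$A, T = 1, n_perm = 50, seed = 1)
  expect_length(res0$components, 0)
  res <- nbs_paired(tens$A, tens$B, T = 1, n_perm = 99, seed = 1)
  if (length(res$component_p) > 0) {
    expect_true(all(res$component_p >= 1 / (1 + 99)))
    expect_true(all(res$component_p <= 1))
  }
  # permutation-p lower bound: 1/(1+5000) < 0.001, matching reported p < 0.001
  expect_lt(1 / (1 + 5000), 0.001)
})

test_that("suprathreshold edges at T = 3.5 are a subset of those at T = 1", {
  tens <- mk_tensors(23, 8, seed = 3, shift_edges = list(c(1, 2), c(2, 3)),
                     shift = 1.5)
  r1 <- nbs_paired(tens$A, tens$B, T = 1, n_perm = 20, seed = 5)
  r35 <- nbs_paired(tens$A, tens$B, T = 3.5, n_perm = 20, seed = 5)
  e1 <- do.call(rbind, lapply(r1$components, function(d) d[c("node_i", "node_j")]))
  e35 <- do.call(rbind, lapply(r35$components, function(d) d[c("node_i", "node_j")]))
  if (!is.null(e35) && nrow(e35) > 0) {
    key1 <- paste(e1$node_i, e1$node_j)
    key35 <- paste(e35$node_i, e35$node_j)
    expect_true(all(key35 %in% key1))
  }
  # reproducibility under a fixed seed
  r1b <- nbs_paired(tens$A, tens$B, T = 1, n_perm = 20, seed = 5)
  expect_identical(r1$null_max, r1b$null_max)
  expect_equal(r1$component_p, r1b$component_p)
})

test_that("significant adjacency marks exactly the significant component edges", {
  tens <- mk_tensors(23, 8, seed = 4, shift_edges = list(c(1, 2), c(2, 3)),
                     shift = 2)
  res <- nbs_paired(tens$A, tens$B, T = 3.5, n_perm = 200, seed = 2)
  adj <- significant_adjacency(res, alpha = 0.05)
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj) == 0))
  k <- sum(vapply(seq_along(res$components), function(i) {
    if (res$component_p[i] < 0.05) res$component_sizes[i] else 0L
  }, integer(1)))
  expect_equal(sum(adj), 2 * k)
  # alpha = 1 admits every suprathreshold edge
  adj_all <- significant_adjacency(res, alpha = 1)
  expect_equal(sum(adj_all) / 2, sum(res$component_sizes))
  # no significant component -> zero matrix
  null_res <- nbs_paired(tens$A, tens$A, T = 1, n_perm = 20, seed = 1)
  expect_true(all(significant_adjacency(null_res) == 0))
})

test_that("adjacency weighting masks connectivity magnitudes idempotently", {
  set.seed(9)
  conn <- matrix(rnorm(16), 4); conn <- (conn + t(conn)) / 2; diag(conn) <- 0
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1L; adj[3, 4] <- adj[4, 3] <- 1L
  w <- apply_adjacency_weights(adj, conn)
  expect_equal(w[1, 2], abs(conn[1, 2]))
  expect_equal(w[1, 3], 0)
  w2 <- apply_adjacency_weights(adj, w)
  expect_equal(unclass(w2), unclass(w))
  expect_true(all(apply_adjacency_weights(matrix(0L, 4, 4), conn) == 0))
  ones <- matrix(1L, 4, 4); diag(ones) <- 0L
  w3 <- apply_adjacency_weights(ones, conn)
  expect_equal(unclass(w3)[upper.tri(conn)], abs(conn)[upper.tri(conn)])
  expect_error(apply_adjacency_weights(adj, conn[1:3, 1:3]))
})

test_that("edge-list export carries component ids and p-values", {
  tens <- mk_tensors(23, 6, seed = 6, shift_edges = list(c(1, 2)), shift = 2)
  res <- nbs_paired(tens$A, tens$B, T = 3.5, n_perm = 100, seed = 3)
  el <- nbs_edge_list(res)
  if (nrow(el) > 0) {
    expect_true(all(c("node_i", "node_j", "t", "component", "p") %in% names(el)))
    expect_true(all(el$t > 3.5))
  }
  empty <- nbs_paired(tens$A, tens$A, T = 1, n_perm = 10, seed = 1)
  expect_equal(nrow(nbs_edge_list(empty)), 0)
})
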