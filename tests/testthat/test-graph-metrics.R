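test_that("clustering matches hand-worked and brute-force cases", {
  expect_equal(clustering(complete_graph(3))$nodal, rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(clustering(complete_graph(3))$mean, 1)
  expect_equal(clustering(path_graph(3))$nodal, rep(0, 3),
               ignore_attr = TRUE)
  # K4 on {1..4} plus pendant chain 4-5, 5-6
  a <- complete_graph(6)
  a[5:6, ] <- 0L; a[, 5:6] <- 0L
  a[4, 5] <- a[5, 4] <- 1L; a[5, 6] <- a[6, 5] <- 1L
  expect_equal(clustering(a)$nodal, oracle_clustering(a),
               ignore_attr = TRUE)
  expect_equal(clustering(a)$nodal[1:3], rep(1, 3), ignore_attr = TRUE)
})

test_that("path length follows the reachable-pairs convention", {
  expect_equal(path_length(complete_graph(4))$mean, 1)
  expect_equal(path_length(path_graph(3))$mean, 4 / 3)
  # two disjoint K2 pairs: unreachable pairs excluded -> L = 1
  two_k2 <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_equal(path_length(two_k2)$mean, 1)
  # edgeless graph: undefined, signalled
  expect_warning(res <- path_length(matrix(0L, 4, 4)), "no edges")
  expect_true(is.na(res$mean))
})

test_that("efficiencies match worked examples and conventions", {
  expect_equal(global_efficiency(complete_graph(5))$global, 1)
  expect_equal(global_efficiency(matrix(0L, 4, 4))$global, 0)
  expect_equal(global_efficiency(path_graph(3))$global, 5 / 6)

  expect_equal(local_efficiency(complete_graph(4))$nodal, rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(local_efficiency(star_graph(5))$nodal, rep(0, 5),
               ignore_attr = TRUE)
  # K4 plus pendant: against the brute-force subgraph oracle
  a <- complete_graph(5)
  a[5, ] <- 0L; a[, 5] <- 0L
  a[4, 5] <- a[5, 4] <- 1L
  expect_equal(local_efficiency(a)$nodal, oracle_local_efficiency(a),
               ignore_attr = TRUE)
})

test_that("betweenness matches enumeration and normalization bounds", {
  b <- betweenness(star_graph(5))
  expect_equal(b$normalized[1], 1)
  expect_equal(b$normalized[-1], rep(0, 4), ignore_attr = TRUE)
  # C4: each node carries half of the opposite pair's two shortest paths
  b4 <- betweenness(cycle_graph(4))
  expect_equal(b4$raw, rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(b4$normalized, rep(0.5 / 3, 4), ignore_attr = TRUE)
  expect_equal(betweenness(complete_graph(6))$raw, rep(0, 6),
               ignore_attr = TRUE)
})

test_that("all metrics equal brute-force oracles on random small graphs", {
  set.seed(555)
  for (i in 1:60) {
    n <- sample(4:7, 1)
    a <- random_connected_graph(n, p_edge = runif(1, 0.3, 0.8))
    expect_equal(clustering(a)$nodal, oracle_clustering(a),
                 ignore_attr = TRUE)
    expect_equal(path_length(a)$mean, oracle_path_length(a))
    expect_equal(global_efficiency(a)$nodal, oracle_global_efficiency(a),
                 ignore_attr = TRUE)
    expect_equal(local_efficiency(a)$nodal, oracle_local_efficiency(a),
                 ignore_attr = TRUE)
    expect_equal(betweenness(a)$raw, oracle_betweenness(a),
                 ignore_attr = TRUE, tolerance = 1e-12)
    d <- distances_matrix(a)
    expect_equal(d, oracle_distances(a), ignore_attr = TRUE)
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:10) {
    a <- random_connected_graph(8, 0.4)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(betweenness(a)$raw, igraph::betweenness(g),
                 ignore_attr = TRUE, tolerance = 1e-12)
    tr <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(clustering(a)$nodal, tr, ignore_attr = TRUE)
    expect_equal(distances_matrix(a), igraph::distances(g),
                 ignore_attr = TRUE)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(321)
  a <- random_connected_graph(10, 0.35)
  perm <- sample(10)
  ap <- a[perm, perm]
  expect_equal(sort(clustering(a)$nodal), sort(clustering(ap)$nodal))
  expect_equal(path_length(a)$mean, path_length(ap)$mean)
  expect_equal(global_efficiency(a)$global, global_efficiency(ap)$global)
  expect_equal(local_efficiency(a)$mean, local_efficiency(ap)$mean)
  expect_equal(sort(round(betweenness(a)$raw, 10)),
               sort(round(betweenness(ap)$raw, 10)))
})

test_that("global efficiency is monotone non-decreasing under edge addition", {
  set.seed(17)
  a <- adj_from_edges(8, list(c(1, 2)))
  e_prev <- global_efficiency(a)$global
  empty <- which(upper.tri(a) & a == 0)
  for (idx in sample(empty, 15)) {
    i <- ((idx - 1) %% 8) + 1; j <- ((idx - 1) %/% 8) + 1
    a[i, j] <- a[j, i] <- 1L
    e_now <- global_efficiency(a)$global
    expect_gte(e_now, e_prev)
    expect_lte(e_now, 1)
    e_prev <- e_now
  }
})

test_that("random references preserve the degree sequence exactly", {
  set.seed(4321)
  a <- random_connected_graph(20, 0.2)
  ref <- random_reference(a, n_random = 20, seed = 7)
  for (adj in ref$adjacencies) {
    expect_equal(sort(rowSums(adj)), sort(rowSums(a)))
    expect_identical(adj, t(adj))
    expect_true(all(diag(adj) == 0))
  }
  expect_false(ref$flagged)
})

test_that("reference generation is deterministic and flags rigid graphs", {
  set.seed(1)
  a <- random_connected_graph(15, 0.3)
  r1 <- random_reference(a, n_random = 5, seed = 42)
  r2 <- random_reference(a, n_random = 5, seed = 42)
  expect_identical(r1$adjacencies, r2$adjacencies)
  expect_identical(r1$C_rand, r2$C_rand)

  # K4 admits no valid double-edge swap: references equal input, flagged
  k4 <- random_reference(complete_graph(4), n_random = 3, seed = 1)
  expect_true(k4$flagged)
  for (adj in k4$adjacencies)
    expect_equal(adj, complete_graph(4), ignore_attr = TRUE)
})

test_that("small-world indices: identity, degenerate case, ring lattice", {
  sw_k4 <- small_world(complete_graph(4), n_random = 5, seed = 3)
  expect_equal(sw_k4$gamma, 1)
  expect_equal(sw_k4$lambda, 1)
  expect_equal(sw_k4$sigma, 1)
  expect_true(sw_k4$flagged)

  set.seed(10)
  a <- random_connected_graph(20, 0.25)
  sw <- small_world(a, n_random = 20, seed = 5)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)

  # 68-node ring lattice, k = 6, 5% rewiring: small-world by construction
  rl <- ring_lattice(68, 6, p_rewire = 0.05, seed = 2)
  sw_rl <- small_world(rl, n_random = 50, seed = 9)
  expect_gt(sw_rl$sigma, 1)
  expect_gt(sw_rl$gamma, 1)
})

test_that("network_metrics bundles the suite consistently", {
  set.seed(6)
  a <- random_connected_graph(12, 0.3)
  m <- network_metrics(a, n_random = 10, seed = 4)
  expect_named(m$global, c("C", "L", "E_global", "E_local",
                           "gamma", "lambda", "sigma"))
  expect_equal(unname(m$global["C"]), clustering(a)$mean)
  expect_equal(unname(m$global["sigma"]),
               unname(m$global["gamma"] / m$global["lambda"]))
  expect_equal(m$nodal$degree, rowSums(a), ignore_attr = TRUE)
  expect_equal(sum(m$nodal$degree), sum(a))
  m0 <- network_metrics(a, n_random = 0)
  expect_named(m0$global, c("C", "L", "E_global", "E_local"))
})
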