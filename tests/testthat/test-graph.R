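test_that("closed-form graphs give the hand-derived metric values", {
  # uniform complete graph, weight 0.5, 4 nodes
  u <- matrix(0.5, 4, 4); diag(u) <- 0
  expect_equal(as.numeric(characteristic_path_length(u)), 2)
  expect_equal(global_efficiency(u), 0.5)
  expect_equal(unname(clustering_weighted(u)$per_node), rep(1, 4))
  expect_equal(unname(eigenvector_centrality(u)), rep(0.5, 4))
  expect_equal(unname(local_efficiency(u)), rep(0.5, 4))

  u1 <- matrix(1, 5, 5); diag(u1) <- 0
  expect_equal(as.numeric(characteristic_path_length(u1)), 1)
  expect_equal(global_efficiency(u1), 1)
  expect_equal(unname(local_efficiency(u1)), rep(1, 5))
  expect_equal(unname(eigenvector_centrality(u1)), rep(1 / sqrt(5), 5))

  # star graph: no triangles anywhere
  st <- matrix(0, 5, 5); st[1, 2:5] <- st[2:5, 1] <- 0.7
  expect_equal(unname(clustering_weighted(st)$per_node), rep(0, 5))
  expect_equal(clustering_weighted(st)$average, 0)
  expect_equal(unname(local_efficiency(st)), rep(0, 5))

  # triangle with weights (1, 1, 0.125): geometric mean (1*1*0.125)^(1/3)
  tr <- matrix(0, 3, 3)
  tr[1, 2] <- tr[2, 1] <- 1
  tr[1, 3] <- tr[3, 1] <- 1
  tr[2, 3] <- tr[3, 2] <- 0.125
  expect_equal(unname(clustering_weighted(tr)$per_node), rep(0.5, 3))

  # 3-node line: indirect route beats the weak direct edge
  ln <- matrix(0, 3, 3)
  ln[1, 2] <- ln[2, 1] <- 1
  ln[2, 3] <- ln[3, 2] <- 1
  ln[1, 3] <- ln[3, 1] <- 0.1
  d <- shortest_path_lengths(ln)
  expect_equal(d[1, 3], 2)
  expect_equal(as.numeric(characteristic_path_length(ln)), mean(c(1, 1, 2)))

  # 3-node path, uniform weights: centrality proportional to (1, sqrt(2), 1)
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 0.8
  expect_equal(unname(eigenvector_centrality(p3)),
               c(0.5, sqrt(2) / 2, 0.5), tolerance = 1e-9)

  expect_error(clustering_weighted(matrix(0, 2, 2)), "3 nodes")
})

test_that("disconnected graphs yield infinite distances and flagged centrality", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  d <- shortest_path_lengths(w)
  expect_true(is.infinite(d[1, 3]))
  expect_equal(attr(characteristic_path_length(w), "n_infinite"), 4)
  expect_equal(global_efficiency(w), mean(c(1, 0, 0, 0, 0, 0.5)))
  expect_warning(ec <- eigenvector_centrality(w), "disconnected")
  expect_equal(sum(ec^2), 1)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "disconnected")
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(20)
  for (rep in 1:12) {
    w <- random_weighted_graph(8, density = if (rep %% 2) 1 else 0.7)
    expect_equal(unname(shortest_path_lengths(w)), minplus_distances(w),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(w), global_efficiency_oracle(w),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(w)), local_efficiency_oracle(w),
                 tolerance = 1e-10)
    expect_equal(unname(clustering_weighted(w)$per_node), clustering_oracle(w),
                 tolerance = 1e-10)
    if (all(igraph::components(igraph::graph_from_adjacency_matrix(
      w > 0, mode = "undirected"))$no == 1))
      expect_equal(unname(eigenvector_centrality(w)),
                   eigencentrality_oracle(w), tolerance = 1e-8)
  }
  # exhaustive path enumeration cross-check on tiny graphs
  set.seed(21)
  for (rep in 1:5) {
    w <- random_weighted_graph(5, density = 0.8)
    expect_equal(unname(shortest_path_lengths(w)), enum_distances(w),
                 tolerance = 1e-10)
  }
})

test_that("metrics respect permutation, scaling and monotonicity properties", {
  set.seed(22)
  w <- random_weighted_graph(7)
  perm <- sample(7)
  wp <- w[perm, perm]
  expect_equal(global_efficiency(wp), global_efficiency(w))
  expect_equal(as.numeric(characteristic_path_length(wp)),
               as.numeric(characteristic_path_length(w)))
  expect_equal(clustering_weighted(wp)$average, clustering_weighted(w)$average)
  expect_equal(unname(local_efficiency(wp)),
               unname(local_efficiency(w)[perm]))
  expect_equal(unname(eigenvector_centrality(wp)),
               unname(eigenvector_centrality(w)[perm]), tolerance = 1e-8)

  # centrality invariant to weight scaling
  expect_equal(unname(eigenvector_centrality(3 * w)),
               unname(eigenvector_centrality(w)), tolerance = 1e-8)

  # raising one weight never lowers global efficiency
  for (rep in 1:5) {
    i <- sample(6, 1); j <- i + 1
    w2 <- w
    w2[i, j] <- w2[j, i] <- w[i, j] + 0.5
    expect_gte(global_efficiency(w2), global_efficiency(w))
  }

  # efficiency bounded by the maximum weight
  expect_lte(global_efficiency(w), max(w))

  expect_error(as_weighted_graph(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(as_weighted_graph(-diag(3) + 0.5), "non-negative")
})

test_that("network_metrics bundles global scalars and nodal vectors", {
  set.seed(23)
  w <- random_weighted_graph(6)
  nm <- network_metrics(w)
  expect_length(nm$local_efficiency, 6)
  expect_equal(nm$avg_clustering, clustering_weighted(w)$average)
  expect_equal(nm$global_efficiency, global_efficiency(w))
  expect_equal(sum(nm$eigenvector_centrality^2), 1)
})
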