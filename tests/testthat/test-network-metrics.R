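path3 <- net_from_adj(rbind(
  c(0, 1, 0),
  c(1, 0, 1),
  c(0, 1, 0)
))

test_that("closed-form metrics on canonical small graphs", {
  complete4 <- net_from_adj(matrix(1, 4, 4) - diag(4))
  star5 <- net_from_adj(rbind(
    c(0, 1, 1, 1, 1),
    c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)
  ))
  triangle <- net_from_adj(matrix(1, 3, 3) - diag(3))

  expect_equal(net_density(complete4), 1)
  expect_equal(net_path_length(complete4), 1)
  expect_equal(net_average_degree(star5), 2 * 4 / 5)
  expect_equal(net_clustering(star5), 0)
  expect_equal(net_clustering(triangle), 1)
  expect_equal(net_path_length(path3), 4 / 3)

  # only connected pairs enter the path length
  two_pairs <- net_from_adj(rbind(
    c(0, 1, 0, 0),
    c(1, 0, 0, 0),
    c(0, 0, 0, 1),
    c(0, 0, 1, 0)
  ))
  expect_equal(net_path_length(two_pairs), 1)
  expect_equal(network_metrics(two_pairs)$n_connected_pairs, 2)

  edgeless <- net_from_adj(matrix(0, 3, 3))
  expect_equal(net_density(edgeless), 0)
  expect_error(net_path_length(edgeless), "without edges")
  expect_warning(met <- network_metrics(edgeless), "no edges")
  expect_true(is.na(met$L))

  # triangle with a pendant vertex: local coefficients 1/3, 1, 1, 0
  tri_pend <- net_from_adj(rbind(
    c(0, 1, 1, 1),
    c(1, 0, 1, 0),
    c(1, 1, 0, 0),
    c(1, 0, 0, 0)
  ))
  expect_equal(net_clustering(tri_pend), bf_clustering(rbind(
    c(0, 1, 1, 1), c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0)
  )))
  expect_equal(net_clustering(tri_pend), (1 / 3 + 1 + 1 + 0) / 4)
})

test_that("betweenness is unnormalised shortest-path load, endpoints excluded", {
  nm <- node_metrics(path3)
  expect_equal(nm$betweenness, c(0, 1, 0))
  complete5 <- net_from_adj(matrix(1, 5, 5) - diag(5))
  expect_true(all(node_metrics(complete5)$betweenness == 0))
})

test_that("all metrics match brute-force oracles on random graphs", {
  for (seed in 1:6) {
    adj <- rand_adj(n = 8 + (seed %% 5), p = 0.35, seed = seed)
    net <- net_from_adj(adj)
    n <- nrow(adj)
    e <- sum(adj) / 2
    met <- suppressWarnings(network_metrics(net))
    expect_equal(met$k, 2 * e / n)
    expect_equal(met$D, 2 * e / (n * (n - 1)))
    expect_equal(met$C, bf_clustering(adj))
    if (e > 0) expect_equal(met$L, bf_avg_path_length(adj))
    expect_equal(node_metrics(net)$betweenness, bf_betweenness(adj))
    expect_equal(sum(node_metrics(net)$degree), 2 * e) # handshake
  }
})

test_that("metrics are invariant under node relabelling", {
  trees <- toy_trees(60, seed = 2)
  met1 <- network_metrics(build_network(trees, "cl"))
  shuffled <- trees[sample(nrow(trees)), ]
  met2 <- network_metrics(build_network(shuffled, "cl"))
  expect_equal(met1[, c("N", "E", "k", "C", "D", "L")], met2[, c("N", "E", "k", "C", "D", "L")])
})

test_that("WCL unweighted characteristics coincide with CL", {
  trees <- toy_trees(100, seed = 4)
  cl <- network_metrics(build_network(trees, "cl"))
  wcl <- network_metrics(build_network(trees, "wcl"))
  expect_equal(wcl$C, cl$C)
  expect_equal(wcl$D, cl$D)
  expect_equal(wcl$L, cl$L)
  expect_equal(wcl$k, cl$k)
  expect_equal(wcl$E, 2 * cl$E)
  # the weighted average degree is the factor times summed CI over N
  w <- build_network(trees, "wcl")
  expect_equal(wcl$k_weighted, 2 * sum(w$edges$weight) / nrow(w$nodes))
  expect_equal(
    network_metrics(w, weighted_degree_factor = 1)$k_weighted,
    sum(w$edges$weight) / nrow(w$nodes)
  )
  # directed and skeleton path lengths agree when every edge is mutual
  expect_equal(net_path_length(w, "directed"), net_path_length(w, "skeleton"))
})

test_that("counts_to_metrics reproduces degree/density identities", {
  m <- counts_to_metrics(271, 1146)
  expect_equal(m$k, 2 * 1146 / 271)
  expect_equal(m$D, 2 * 1146 / (271 * 270))
  expect_error(counts_to_metrics(1, 0), "2 nodes")
})

test_that("spline fields interpolate and reproduce affine surfaces", {
  trees <- toy_trees(25, seed = 8, crowns = FALSE)
  const <- interpolate_metric(trees, rep(3.3, 25), plot_window(50, 50), spacing = 10)
  expect_lt(max(abs(const$value - 3.3)), 1e-8)

  ramp_vals <- 0.2 * trees$x - 0.5 * trees$y + 1
  ramp <- interpolate_metric(trees, ramp_vals, plot_window(50, 50), spacing = 5)
  expect_lt(max(abs(ramp$value - (0.2 * ramp$x - 0.5 * ramp$y + 1))), 1e-6)

  # with zero smoothing the surface passes through the data
  bumpy <- sin(trees$x / 8) + cos(trees$y / 11)
  at_nodes <- interpolate_metric(trees, bumpy,
    window = plot_window(50, 50),
    smoothing = 0, at = trees
  )
  expect_lt(max(abs(at_nodes$value - bumpy)), 1e-4)

  collinear <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  expect_error(interpolate_metric(collinear, 1:10, plot_window(50, 50)), "collinear")
  expect_error(interpolate_metric(trees[1:3, ], 1:3, plot_window(50, 50)), "at least 4")
})
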