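# The fixed small graphs here are ones where greedy optimization is known
# (by exhaustive enumeration in the oracle) to attain the global
# modularity maximum, so the detected Q can be compared to the optimum.

test_that("louvain attains the exhaustive-search optimum on small benchmark graphs", {
  graphs <- list(two_triangle = two_triangle_graph(),
                 cliques = clique_pair_graph(4, 3),
                 k5 = {
                   W <- matrix(1, 5, 5) - diag(5)
                   rownames(W) <- colnames(W) <- paste0("n", 1:5)
                   W
                 })
  for (nm in names(graphs)) {
    W <- graphs[[nm]]
    best <- oracle_best_partition(W)
    part <- louvain(W, seed = 3)
    expect_equal(part$Q, best$q, tolerance = 1e-9)
    expect_equal(adjusted_rand_index(part$assignment, best$partition), 1)
  }
})

test_that("exhaustive enumeration confirms the two-triangle optimum over all 203 partitions", {
  W <- two_triangle_graph()
  best <- oracle_best_partition(W)
  expect_equal(best$n_partitions, 203)
  expect_equal(best$q, 5 / 14, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(best$partition, c(1, 1, 1, 2, 2, 2)), 1)
})

test_that("louvain collapses a complete graph into one community with Q = 0", {
  W <- matrix(1, 5, 5) - diag(5)
  part <- louvain(W, seed = 1)
  expect_length(unique(part$assignment), 1)
  expect_equal(part$Q, 0)
})

test_that("louvain never scores below the singleton start and honours its stored Q", {
  set.seed(23)
  for (rep in 1:5) {
    pl <- planted_block_graph(c(6, 6), 0.7, 0.1, seed = rep)
    part <- louvain(pl$W, seed = rep)
    expect_gte(part$Q, modularity_q(pl$W, seq_len(nrow(pl$W))))
    expect_equal(part$Q, modularity_q(pl$W, part$assignment),
                 tolerance = 1e-12)
  }
  expect_error(louvain(matrix(0, 3, 3)), "zero")
})

test_that("louvain recovers planted 2-block structure (median ARI over 20 seeds >= 0.9)", {
  aris <- vapply(1:20, function(s) {
    pl <- planted_block_graph(c(15, 15), p_in = 0.5, p_out = 0.05, seed = s)
    part <- louvain(pl$W, seed = s)
    adjusted_rand_index(part$assignment, pl$truth)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})

test_that("girvan-newman removes the bridge first and recovers the triangles", {
  W <- two_triangle_graph()
  # the bridge c-d is the unique betweenness maximum; verified against
  # exact enumeration over all 15 node pairs
  eb <- edge_betweenness(W)
  oracle_eb <- oracle_edge_betweenness(W)
  expect_equal(eb, oracle_eb, tolerance = 1e-9)
  expect_equal(unname(which(eb == max(eb), arr.ind = TRUE)[1, ]), c(4, 3))
  part <- girvan_newman(W)
  expect_equal(part$Q, 5 / 14, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(part$assignment, c(1, 1, 1, 2, 2, 2)), 1)
})

test_that("girvan-newman on a two-node path returns the single community with Q = 0", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  part <- girvan_newman(W)
  expect_length(unique(part$assignment), 1)
  expect_equal(part$Q, 0)
})

test_that("walktrap recovers the triangles and exact components of disconnected cliques", {
  part <- walktrap(two_triangle_graph(), t = 4)
  expect_equal(part$Q, 5 / 14, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(part$assignment, c(1, 1, 1, 2, 2, 2)), 1)
  W <- clique_pair_graph(4, 3)
  pc <- walktrap(W, t = 4)
  expect_equal(adjusted_rand_index(pc$assignment, rep(1:2, c(4, 3))), 1)
  expect_error(walktrap(two_triangle_graph(), t = 0), "t must be >= 1")
})

test_that("walktrap tolerates isolated nodes as their own communities", {
  W <- matrix(0, 5, 5)
  W[1:4, 1:4] <- clique_pair_graph(2, 2)
  rownames(W) <- colnames(W) <- paste0("n", 1:5)
  part <- walktrap(W)
  expect_length(part$assignment, 5)
  expect_false(part$assignment["n5"] %in% part$assignment[1:4])
})

test_that("walktrap agrees with an independent reference implementation on the fixed graph", {
  skip_if_not_installed("igraph")
  W <- two_triangle_graph()
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::membership(igraph::cluster_walktrap(g, steps = 4))
  part <- walktrap(W, t = 4)
  expect_equal(adjusted_rand_index(part$assignment, as.integer(ref)), 1)
})

test_that("all three algorithms agree on the benchmark graphs", {
  for (W in list(two_triangle_graph(), clique_pair_graph(4, 4))) {
    parts <- lapply(c("louvain", "girvan_newman", "walktrap"),
                    function(a) detect_communities(W, a, seed = 2))
    expect_equal(adjusted_rand_index(parts[[1]]$assignment,
                                     parts[[2]]$assignment), 1)
    expect_equal(adjusted_rand_index(parts[[1]]$assignment,
                                     parts[[3]]$assignment), 1)
  }
})

test_that("adjusted Rand index has its defining properties", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(2, 2, 3, 3, 1, 1)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, b), 1)   # relabelling is invisible
  expect_equal(adjusted_rand_index(a, 1:6), adjusted_rand_index(1:6, a))
  # all-singletons against a real partition agrees no better than chance
  expect_lte(adjusted_rand_index(a, 1:6), 0)
  named_a <- setNames(a, letters[1:6])
  named_b <- setNames(b[c(2, 1, 3, 4, 6, 5)], letters[c(2, 1, 3, 4, 6, 5)])
  expect_equal(adjusted_rand_index(named_a, named_b), 1)
})
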