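test_that("state networks average assigned windows exactly", {
  z <- list(matrix(0.2, 3, 3), matrix(0.4, 3, 3), matrix(0.9, 3, 3))
  labs <- c(1, 1, 2)
  net <- state_network(z, labs, 1)
  expect_equal(net[1, 2], 0.3)
  expect_equal(diag(net), rep(0, 3))
  net2 <- state_network(z, labs, 2)
  expect_equal(net2[1, 3], 0.9)
  expect_message(expect_null(state_network(z, labs, 3)), "never visited")

  # random series vs loop-and-average oracle
  set.seed(61)
  z <- replicate(9, { m <- matrix(rnorm(25), 5, 5); m + t(m) },
                 simplify = FALSE)
  labs <- sample.int(2, 9, replace = TRUE)
  net <- state_network(z, labs, 1)
  oracle <- matrix(0, 5, 5)
  for (i in which(labs == 1)) oracle <- oracle + z[[i]]
  oracle <- oracle / sum(labs == 1)
  diag(oracle) <- 0
  expect_equal(net, oracle, tolerance = 1e-12)
})

test_that("sparsity thresholding keeps the top-k edges with a fixed tie policy", {
  w <- matrix(0, 4, 4)
  vals <- c(6, 5, 4, 3, 2, 1)  # row-major upper: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  w[upper.tri(w)] <- 0
  w <- devectorize_fc(vals, 4)
  a <- threshold_by_sparsity(w, 0.5)
  expect_equal(sum(a) / 2, 3)
  expect_equal(a[1, 2] + a[1, 3] + a[1, 4], 3)  # the 3 largest

  a2 <- threshold_by_sparsity(w, 1 / 3)
  expect_equal(sum(a2) / 2, 2)
  expect_equal(c(a2[1, 2], a2[1, 3]), c(1, 1))

  # all weights equal: first k edges in row-major order retained
  weq <- devectorize_fc(rep(1, 6), 4)
  aeq <- threshold_by_sparsity(weq, 0.5)
  expect_equal(vectorize_fc(aeq), c(1, 1, 1, 0, 0, 0))
})

test_that("hop distances match the matrix-power oracle", {
  p3 <- path_graph(3)
  expect_equal(all_pairs_distances(p3)[1, 3], 2)

  two_dyads <- devectorize_fc(c(1, 0, 0, 0, 0, 1), 4)
  d <- all_pairs_distances(two_dyads)
  expect_equal(d[1, 3], Inf)
  expect_equal(d[1, 2], 1)

  set.seed(62)
  for (i in 1:20) {
    a <- random_adj(sample(4:12, 1), runif(1, 0.2, 0.7))
    expect_equal(all_pairs_distances(a), oracle_distances(a))
  }
})

test_that("global efficiency has its closed-form values", {
  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
})

test_that("clustering, degree and local efficiency match small closed forms", {
  k3 <- complete_graph(3)
  expect_equal(nodal_clustering(k3), rep(1, 3))
  expect_equal(nodal_degree(k3), rep(2L, 3))

  st <- star_graph(4)
  expect_equal(nodal_clustering(st)[1], 0)
  expect_equal(nodal_degree(st)[1], 4L)
  expect_equal(nodal_local_efficiency(st)[1], 0)

  k4 <- complete_graph(4)
  expect_equal(nodal_local_efficiency(k4), rep(1, 4))
  expect_equal(local_efficiency(k4), 1)
})

test_that("betweenness matches path-enumeration cases", {
  p3 <- path_graph(3)
  expect_equal(betweenness_centrality(p3), c(0, 1, 0))
  st <- star_graph(4)
  expect_equal(betweenness_centrality(st)[1], choose(4, 2))
  expect_equal(betweenness_centrality(st)[-1], rep(0, 4))
})

test_that("all metrics equal brute-force oracles on exhaustive small graphs", {
  # every labeled graph on 4 nodes, plus seeded graphs at n = 5..8
  graphs <- all_graphs(4)
  set.seed(63)
  for (n in 5:8) {
    graphs <- c(graphs, replicate(15, random_adj(n, runif(1, 0.25, 0.8),
                                                 connected = TRUE),
                                  simplify = FALSE))
  }
  for (a in graphs) {
    expect_equal(nodal_degree(a), as.integer(oracle_degree(a)))
    expect_equal(nodal_clustering(a), oracle_clustering(a))
    expect_equal(nodal_local_efficiency(a), oracle_local_efficiency(a))
    expect_equal(global_efficiency(a), oracle_global_efficiency(a))
    expect_equal(betweenness_centrality(a), oracle_betweenness(a))
  }
})

test_that("graph metrics equal oracles on 50 random graphs up to n = 12", {
  set.seed(64)
  for (i in 1:50) {
    a <- random_adj(sample(6:12, 1), runif(1, 0.2, 0.6))
    expect_equal(nodal_degree(a), as.integer(oracle_degree(a)))
    expect_equal(nodal_clustering(a), oracle_clustering(a))
    expect_equal(nodal_local_efficiency(a), oracle_local_efficiency(a))
    expect_equal(global_efficiency(a), oracle_global_efficiency(a))
    expect_equal(betweenness_centrality(a), oracle_betweenness(a))
  }
})

test_that("tree betweenness equals the pair-separation oracle", {
  set.seed(65)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    a <- random_tree(n)
    bc <- betweenness_centrality(a)
    # removing v splits a tree into components; pairs separated = product sums
    oracle <- vapply(1:n, function(v) {
      sub <- a[-v, -v, drop = FALSE]
      d <- oracle_distances(sub)
      comp_sizes <- c()
      left <- 1:(n - 1)
      while (length(left)) {
        grp <- which(is.finite(d[left[1], ]))
        comp_sizes <- c(comp_sizes, length(grp))
        left <- setdiff(left, grp)
      }
      (sum(comp_sizes)^2 - sum(comp_sizes^2)) / 2
    }, numeric(1))
    expect_equal(bc, oracle)
  }
})

test_that("efficiency metrics and degree obey sweep invariants", {
  set.seed(66)
  w <- matrix(rnorm(30 * 30), 30, 30)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  sweep_levels <- seq(0.1, 0.4, by = 0.05)
  prev_ge <- 0
  prev_le <- 0
  for (sp in sweep_levels) {
    a <- threshold_by_sparsity(w, sp)
    expect_equal(sum(nodal_degree(a)), sum(a))  # 2x edges
    ge <- global_efficiency(a)
    expect_gte(ge, prev_ge - 1e-12)  # nested graphs: GE nondecreasing
    prev_ge <- ge
  }
})

test_that("small-worldness behaves at its reference points", {
  # complete graph: nulls identical, gamma = lambda = sigma = 1
  sw <- small_worldness(complete_graph(8), n_null = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$gamma, 1)

  # Watts-Strogatz ring: strongly small-world
  set.seed(67)
  g <- igraph::sample_smallworld(1, 100, 3, 0.1)
  a <- unname(igraph::as_adjacency_matrix(igraph::simplify(g),
                                          sparse = FALSE))
  sw <- small_worldness(a, n_null = 20, seed = 2)
  expect_gt(sw$sigma, 1)

  # a rewired null against its own ensemble: sigma near 1
  gn <- igraph::rewire(igraph::sample_gnp(40, 0.2),
                       igraph::keeping_degseq(niter = 1000))
  an <- unname(igraph::as_adjacency_matrix(gn, sparse = FALSE))
  swn <- small_worldness(an, n_null = 30, seed = 3)
  expect_lt(abs(swn$sigma - 1), 0.1)
})

test_that("metric AUC is the trapezoidal integral over the sweep", {
  sp <- seq(0.10, 0.40, by = 0.01)
  expect_equal(metric_auc(sp, rep(1, 31)), 0.30)
  ramp <- seq(0, 1, length.out = 31)
  expect_equal(metric_auc(sp, ramp), 0.15)

  set.seed(68)
  y <- runif(31)
  oracle <- 0
  for (i in 1:30) oracle <- oracle + 0.01 * (y[i] + y[i + 1]) / 2
  expect_equal(metric_auc(sp, y), oracle, tolerance = 1e-12)

  expect_error(metric_auc(sp[1:5], rep(1, 4)))
})

test_that("the sweep table covers all metrics and aggregates by AUC", {
  set.seed(69)
  w <- matrix(rnorm(100), 10, 10)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  tbl <- graph_metric_sweep(w, sparsities = seq(0.1, 0.4, 0.1))
  expect_setequal(unique(tbl$metric), c("ge", "le", "ne", "ncc", "dc", "bc"))
  expect_equal(sum(is.na(tbl$node)), 2 * 4)  # 2 global metrics x 4 levels
  auc <- sweep_auc(tbl)
  expect_equal(nrow(auc), 2 + 4 * 10)  # global + nodal combinations
  expect_true(all(is.finite(auc$auc)))
})
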