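test_that("k-core profile matches iterative pruning on hand cases", {
  # a triangle with a pendant node: 1-core has 4 nodes, 2-core the triangle
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4), directed = FALSE)
  prof <- k_core_profile(g)
  expect_equal(prof$k, 1:2)
  expect_equal(prof$size, c(4, 3))
  expect_equal(k_core_profile(fixture_graph("clique_4"))$size, c(4, 4, 4))
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(nrow(k_core_profile(empty)), 0)
})

test_that("k-core profile is nonincreasing and nested on random graphs", {
  set.seed(31)
  for (i in 1:5) {
    g <- igraph::sample_gnm(80, 160)
    prof <- k_core_profile(g)
    expect_true(all(diff(prof$size) <= 0))
    cores <- igraph::coreness(g)
    for (k in prof$k)
      expect_equal(prof$size[prof$k == k], sum(cores >= k))
  }
})

test_that("efficiency matches hand values and the igraph oracle", {
  eff <- efficiency(fixture_graph("path_3"))
  expect_equal(eff$E, 5 / 6)            # (1 + 1 + 1/2) / 3
  expect_equal(eff$l_max, 2)
  expect_equal(eff$n_pairs, 6)          # ordered pairs
  # disconnected: two K2 components; connected-pairs average is 1
  g2 <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_equal(efficiency(g2)$E, 1)
  expect_equal(efficiency(g2, all_pairs = TRUE)$E, 4 / 12)
  # random graph against a direct distance-matrix recomputation
  set.seed(32)
  g <- igraph::sample_gnm(60, 100)
  d <- igraph::distances(g, algorithm = "unweighted")
  diag(d) <- Inf
  fin <- is.finite(d)
  expect_equal(efficiency(g)$E, mean(1 / d[fin]))
  expect_equal(efficiency(g)$l_max, max(d[fin]))
  expect_error(efficiency(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("sampled efficiency approximates the exact value", {
  g <- erdos_renyi_graph(300, 6, seed = 33)
  exact <- efficiency(g)$E
  est <- efficiency(g, sample_sources = 100, seed = 34)
  expect_true(est$sampled)
  expect_equal(est$E, exact, tolerance = 0.05)
})

test_that("efficiency_under_removal reports valid grids and the p = 1 limit", {
  g <- erdos_renyi_graph(150, 5, seed = 35)
  tab <- efficiency_under_removal(g, "random_edge", p_grid = c(0.2, 0.6, 1),
                                  n_runs = 5, seed = 36)
  expect_equal(names(tab), c("p", "efficiency", "n_ok"))
  expect_equal(tab$efficiency[tab$p == 1], efficiency(g)$E)
  expect_true(all(tab$efficiency > 0 & tab$efficiency <= 1))
  expect_true(all(tab$n_ok <= 5))
  # on a clique the remnant stays connected, so sparser means longer paths
  # (lower connected-pairs efficiency); note this is NOT guaranteed for
  # fragmenting graphs, where surviving pairs are conditionally close
  k <- fixture_graph("clique_20")
  tabk <- efficiency_under_removal(k, "random_edge", p_grid = c(0.5, 1),
                                   n_runs = 10, seed = 37)
  expect_equal(tabk$efficiency[2], 1)
  expect_lt(tabk$efficiency[1], 1)
  # p = 0 yields no connected pairs anywhere: NA with n_ok = 0
  tab0 <- efficiency_under_removal(g, "random_node", p_grid = 0, n_runs = 2,
                                   seed = 38)
  expect_true(is.na(tab0$efficiency))
  expect_equal(tab0$n_ok, 0)
})

test_that("Molloy-Reed threshold: hand values and error branch", {
  expect_equal(molloy_reed_threshold(degrees = rep(3, 10)), 0.5)
  # distribution form equals sequence form moments
  expect_equal(molloy_reed_threshold(k = c(2, 4), pk = c(0.5, 0.5)),
               molloy_reed_threshold(degrees = c(2, 4)))
  # pk is normalized internally
  expect_equal(molloy_reed_threshold(k = c(2, 4), pk = c(2, 2)),
               molloy_reed_threshold(k = c(2, 4), pk = c(0.5, 0.5)))
  expect_error(molloy_reed_threshold(degrees = rep(1, 5)), "undefined")
  expect_error(molloy_reed_threshold(degrees = 1:3, k = 1:3, pk = rep(1, 3)),
               "not both")
  expect_error(molloy_reed_threshold(), "need")
})
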