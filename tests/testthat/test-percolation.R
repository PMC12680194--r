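test_that("removal plans have the documented structure", {
  g <- star4()   # center node 1, leaves 2..4
  p_edge <- make_removal_plan(g, "random_edge", seed = 1)
  expect_s3_class(p_edge, "removal_plan")
  expect_setequal(p_edge$addition_order, 1:3)
  p_node <- make_removal_plan(g, "random_node", seed = 1)
  expect_setequal(p_node$addition_order, 1:4)
  p_t <- make_removal_plan(g, "targeted_degree", seed = 1)
  # center has the unique maximum degree: removed first = added last
  expect_equal(p_t$addition_order[4], 1)
  deg <- igraph::degree(g)
  expect_true(all(diff(deg[p_t$addition_order]) >= 0))
})

test_that("targeted tie-break is uniform on a regular graph", {
  g <- cycle5()   # 2-regular: all nodes tied
  first_removed <- vapply(1:1000, function(s) {
    plan <- make_removal_plan(g, "targeted_degree", seed = s)
    plan$addition_order[5]   # last added = first removed
  }, integer(1))
  counts <- tabulate(first_removed, 5)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("single-run trajectories match hand calculations", {
  g <- fixture_graph("clique_3")
  plan <- make_removal_plan(g, "random_edge", seed = 3)
  traj <- newman_ziff_run(g, plan)
  expect_equal(traj, c(1, 2, 3, 3))   # any K3 edge order gives this
  # node mode on P4, order-independent endpoints
  g <- path4()
  plan_n <- make_removal_plan(g, "random_node", seed = 4)
  traj_n <- newman_ziff_run(g, plan_n)
  expect_equal(traj_n[1], 0)
  expect_equal(traj_n[5], 4)
  expect_true(all(diff(traj_n) >= 0))
  expect_error(newman_ziff_run(cycle5(), plan_n), "does not match")
})

test_that("K3 edge curve and R are exact", {
  g <- fixture_graph("clique_3")
  cv <- ensemble_curves(g, "random_edge", n_runs = 20, seed = 1)
  expect_equal(cv$mean_lcc, c(1, 2, 3, 3))   # deterministic for K3
  expect_equal(cv$p, (0:3) / 3)
  expect_equal(robustness_R(cv), mean(c(1, 2, 3, 3) / 3))  # 0.75
  expect_equal(cv$chi, rep(0, 4))
})

test_that("f_threshold follows the supremum-over-grid convention", {
  g <- fixture_graph("clique_3")
  cv <- ensemble_curves(g, "random_edge", n_runs = 5, seed = 1)
  # x*N = 0.03 < 1 <= every grid value: condition holds nowhere
  ft <- f_threshold(cv, x = 0.01)
  expect_equal(ft$p_x, 0)
  expect_equal(ft$f_x, 1)
  # mean curve (1,2,3,3)/N with N=3: below 0.67*3=2.01 up to n=1 (p=1/3)
  ft2 <- f_threshold(cv, x = 0.67)
  expect_equal(ft2$p_x, 1 / 3)
  expect_equal(ft2$f_x, 2 / 3)
})

test_that("ensemble curves are reproducible under a seed", {
  g <- erdos_renyi_graph(100, 4, seed = 9)
  c1 <- ensemble_curves(g, "random_node", 30, seed = 7)
  c2 <- ensemble_curves(g, "random_node", 30, seed = 7)
  expect_identical(c1$mean_lcc, c2$mean_lcc)
  expect_identical(c1$chi, c2$chi)
})

test_that("susceptibility peak extraction validates input and finds peaks", {
  g <- erdos_renyi_graph(400, 5, seed = 21)
  c1 <- ensemble_curves(g, "random_edge", n_runs = 1, seed = 3)
  expect_error(susceptibility_peaks(c1), "at least 2 runs")
  cv <- ensemble_curves(g, "random_edge", n_runs = 60, seed = 3)
  pk <- susceptibility_peaks(cv, window = 21)
  expect_true(all(c("p_star", "chi_star", "f_star") %in% names(pk)))
  expect_equal(pk$f_star, 1 - pk$p_star)
  expect_gte(nrow(pk), 1)
})

test_that("robustness summary bundles the measures and prints", {
  g <- erdos_renyi_graph(200, 4, seed = 2)
  cv <- ensemble_curves(g, "random_edge", 30, seed = 2)
  s <- robustness_summary(cv, x = 0.05)
  expect_s3_class(s, "robustness_summary")
  expect_equal(s$f_x, 1 - s$p_x)
  expect_equal(s$R, robustness_R(cv))
  expect_output(print(s), "Robustness summary")
})

test_that("write_curve_csv produces the documented columns", {
  g <- fixture_graph("clique_3")
  cv <- ensemble_curves(g, "random_edge", 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  tab <- utils::read.csv(path)
  expect_equal(names(tab),
               c("n", "p", "mean_lcc", "second_moment_lcc", "chi"))
  expect_equal(tab$mean_lcc, c(1, 2, 3, 3))
})
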