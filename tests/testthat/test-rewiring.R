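test_that("argument validation", {
  g <- erdos_renyi_graph(50, 4, seed = 1)
  expect_error(rewire_nncrn(g, 3), "distance")
  expect_error(rewire_nncrn(path4(), 1, lazy_prob = 2), "lazy_prob")
  expect_error(rewire_nncrn(igraph::make_graph(c(1, 2), directed = FALSE), 1),
               "at least two edges")
})

test_that("acceptance probability formula at spot values", {
  # J = 0: every admissible proposal is accepted (exp(0) = 1)
  expect_equal(min(1, exp(0 * 0.3)), 1)
  # J_abs = 10, delta r = -0.1 -> exp(-1)
  expect_equal(min(1, exp(10 * -0.1)), exp(-1))
  # empirical check at J = 0: no metropolis rejections ever
  g <- erdos_renyi_graph(100, 4, seed = 2)
  res <- rewire_nncrn(g, 1, J = 0, budget_sweeps = 20, trace_every = 0,
                      seed = 3)
  expect_equal(res$counts[["rejected_metropolis"]], 0)
})

test_that("budget accounting: outcome counts sum to the proposal budget", {
  g <- erdos_renyi_graph(100, 4, seed = 4)
  m <- igraph::ecount(g)
  res <- rewire_nncrn(g, 1, J = 1, budget_sweeps = 13, trace_every = 0,
                      seed = 5)
  expect_equal(sum(unlist(res$counts)), res$budget)
  expect_equal(res$budget, round(13 * m))
  # lazy_prob = 1 performs no proposals at all
  res0 <- rewire_nncrn(g, 1, J = 1, budget_sweeps = 2, lazy_prob = 1,
                       trace_every = 0, seed = 5)
  expect_equal(res0$counts[["rejected_lazy"]], res0$budget)
  expect_identical(as_edge_matrix(res0$graph), as_edge_matrix(g))
})

test_that("distance-1 chain preserves the degree sequence and reports r", {
  g <- erdos_renyi_graph(300, 5, seed = 6)
  res <- rewire_nncrn(g, 1, J = 2, budget_sweeps = 50, trace_every = 0,
                      seed = 7)
  expect_identical(sort(igraph::degree(res$graph)),
                   sort(igraph::degree(g)))
  expect_equal(res$r1, pearson_r_at_distance(res$graph, 1),
               tolerance = 1e-9)
  expect_equal(res$r2, pearson_r_at_distance(res$graph, 2),
               tolerance = 1e-9)
  expect_gt(res$r1, pearson_r_at_distance(g, 1))   # J > 0 raised r1
})

test_that("J tilts r1 in the documented direction; flip_sign flips it", {
  g <- erdos_renyi_graph(300, 5, seed = 8)
  r_pos <- rewire_nncrn(g, 1, J = 2, budget_sweeps = 60, trace_every = 0,
                        seed = 9)$r1
  r_neg <- rewire_nncrn(g, 1, J = -2, budget_sweeps = 60, trace_every = 0,
                        seed = 9)$r1
  expect_gt(r_pos, 0.2)
  expect_lt(r_neg, -0.2)
  r_flip <- rewire_nncrn(g, 1, J = 2, budget_sweeps = 60, trace_every = 0,
                         flip_sign = TRUE, seed = 9)$r1
  expect_lt(r_flip, -0.2)
})

test_that("distance-2 chain preserves the joint degree profile exactly", {
  g <- erdos_renyi_graph(200, 5, seed = 10)
  res <- rewire_nncrn(g, 2, J = 1, budget_sweeps = 40, trace_every = 0,
                      seed = 11)
  expect_true(audit_constraints(g, res$graph))
  expect_gt(res$counts[["applied"]], 0)
  expect_equal(res$r1, pearson_r_at_distance(g, 1), tolerance = 1e-9)
})

test_that("forward and backward swap previews satisfy detailed balance", {
  set.seed(20)
  g <- igraph::sample_gnm(40, 80)
  em <- igraph::as_edgelist(g)
  found_nonzero <- FALSE
  checked <- 0
  for (i in 1:200) {
    e <- sample(nrow(em), 2)
    a <- em[e[1], ]; b <- em[e[2], ]
    sw <- swap_edges(g, a, b)
    if (!sw$applied) next
    for (l in 1:2) {
      fwd <- delta_r_for_swap(g, l, a, b)
      # the inverse swap on the swapped graph returns to the original state
      bwd <- delta_r_for_swap(sw$graph, l, c(a[1], b[2]), c(b[1], a[2]))
      expect_equal(bwd$r_next, fwd$r_prev, tolerance = 1e-9)
      expect_equal(bwd$r_prev, fwd$r_next, tolerance = 1e-9)
      dr <- fwd$r_next - fwd$r_prev
      J <- 2.5
      # MH ratio identity: a(G->G') / a(G'->G) = exp(J * (r' - r))
      expect_equal(min(1, exp(J * dr)) / min(1, exp(-J * dr)), exp(J * dr),
                   tolerance = 1e-12)
      if (abs(dr) > 1e-6) found_nonzero <- TRUE
    }
    checked <- checked + 1
    if (checked >= 50) break
  }
  expect_gte(checked, 20)
  expect_true(found_nonzero)
})

test_that("trace is thinned as requested and matches the final state", {
  g <- erdos_renyi_graph(100, 4, seed = 12)
  res <- rewire_nncrn(g, 1, J = 1, budget_sweeps = 10, trace_every = 50,
                      seed = 13)
  expect_true(all(c("proposal_index", "r1", "r2") %in% names(res$trace)))
  expect_equal(nrow(res$trace), floor(res$budget / 50))
  expect_equal(utils::tail(res$trace$r1, 1), res$r1, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path)
  tab <- utils::read.csv(path)
  expect_equal(names(tab), c("proposal_index", "r1", "r2"))
  expect_equal(nrow(tab), nrow(res$trace))
})

test_that("chains are reproducible under a seed", {
  g <- erdos_renyi_graph(150, 4, seed = 14)
  a <- rewire_nncrn(g, 2, J = 1, budget_sweeps = 10, trace_every = 0,
                    seed = 15)
  b <- rewire_nncrn(g, 2, J = 1, budget_sweeps = 10, trace_every = 0,
                    seed = 15)
  expect_identical(as_edge_matrix(a$graph), as_edge_matrix(b$graph))
  expect_identical(a$counts, b$counts)
})

test_that("estimate_r2ext is near zero for uncorrelated networks", {
  g <- erdos_renyi_graph(400, 5, seed = 16)
  est <- estimate_r2ext(g, n_samples = 5, burnin_sweeps = 30,
                        spacing_sweeps = 5, seed = 17)
  expect_length(est$samples, 5)
  expect_lt(abs(est$mean), 0.05)
  expect_false(is.na(est$sd))
})
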