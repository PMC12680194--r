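test_that("derive_seed is deterministic, in range, and sensitive to inputs", {
  s <- derive_seed(1, 2, 3, 4)
  expect_identical(s, derive_seed(1, 2, 3, 4))
  expect_true(s >= 1 && s <= 2147483646)
  grid <- expand.grid(i1 = 0:3, i2 = 0:3, rep = 1:10)
  seeds <- mapply(derive_seed, 1, grid$i1, grid$i2, grid$rep)
  expect_equal(anyDuplicated(seeds), 0)
  expect_false(derive_seed(2, 2, 3, 4) == s)
})

test_that("experiment_config validates its arguments", {
  cfg <- experiment_config()
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$n, 2000)
  expect_error(experiment_config(family = "lattice"))
  expect_error(experiment_config(percolation_modes = "avalanche"))
  expect_error(experiment_config(threshold_x = 0))
})

test_that("run_grid produces the documented rows and is reproducible", {
  cfg <- experiment_config(n = 150, mean_degree = 4,
                           J1_values = c(-1, 1), J2_values = 0,
                           realizations = 2, budget_sweeps = 10,
                           percolation_runs = 10, master_seed = 7,
                           audit_constraints = TRUE)
  res <- run_grid(cfg)
  expect_equal(nrow(res), 2 * 2 * 1)
  expect_true(all(c("J1", "J2", "realization", "seed", "r1", "r2", "mode",
                    "f_x", "p_x", "R", "n_peaks", "p_star", "error")
                  %in% names(res)))
  expect_true(all(is.na(res$error)))
  expect_true(all(res$mode == "random_edge"))
  res2 <- run_grid(cfg)
  expect_equal(res, res2)
})

test_that("run_grid archives networks when requested", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config(n = 60, mean_degree = 4, J1_values = 0,
                           J2_values = 0, realizations = 1,
                           budget_sweeps = 5, percolation_runs = 5,
                           master_seed = 3, archive_dir = dir)
  run_grid(cfg)
  files <- list.files(dir, pattern = "\\.edges$")
  expect_length(files, 1)
  g <- read_edgelist(file.path(dir, files[1]))
  expect_equal(igraph::ecount(g), round(60 * 4 / 2))
})

test_that("audit_constraints flags violated constraints", {
  g1 <- erdos_renyi_graph(100, 4, seed = 1)
  expect_true(audit_constraints(g1, g1))
  g_other <- erdos_renyi_graph(100, 4, seed = 2)
  expect_error(audit_constraints(g1, g_other), "constraint audit failed")
  # distance-2 chain output passes by construction
  g2 <- rewire_nncrn(g1, 2, J = 2, budget_sweeps = 20, trace_every = 0,
                     seed = 3)$graph
  expect_true(audit_constraints(g1, g2))
})

test_that("single-realization cells report sd = 0 and CI half-width 0", {
  cfg <- experiment_config(n = 80, mean_degree = 4, J1_values = 0,
                           J2_values = 0, realizations = 1,
                           budget_sweeps = 5, percolation_runs = 5,
                           master_seed = 11)
  s <- summarize_grid(run_grid(cfg))
  expect_equal(nrow(s), 1)
  expect_equal(s$r1_sd, 0)
  expect_equal(s$r1_ci3se, 0)
  expect_equal(s$f_x_sd, 0)
})

test_that("run_grid writes JSON-lines progress logs when configured", {
  log <- withr::local_tempfile(fileext = ".jsonl")
  cfg <- experiment_config(n = 80, mean_degree = 4, J1_values = 0,
                           J2_values = c(0, 1), realizations = 2,
                           budget_sweeps = 5, percolation_runs = 5,
                           master_seed = 13, log_file = log)
  run_grid(cfg)
  lines <- readLines(log)
  expect_length(lines, 4)              # one line per completed cell
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("time", "J1", "J2", "realization", "seed", "r1", "r2",
                    "acceptance_rate") %in% names(rec)))
  expect_true(rec$acceptance_rate >= 0 && rec$acceptance_rate <= 1)
})

test_that("summarize_grid aggregates per cell with 3 SE half-widths", {
  cfg <- experiment_config(n = 100, mean_degree = 4, J1_values = c(-1.5, 0),
                           J2_values = 0, realizations = 3,
                           budget_sweeps = 5, percolation_runs = 5,
                           master_seed = 9)
  res <- run_grid(cfg)
  s <- summarize_grid(res)
  expect_equal(nrow(s), 2)
  expect_equal(s$n, c(3, 3))
  sel <- res$J1 == -1.5
  expect_equal(s$r1_mean[s$J1 == -1.5], mean(res$r1[sel]))
  expect_equal(s$r1_ci3se[s$J1 == -1.5],
               3 * stats::sd(res$r1[sel]) / sqrt(3))
  dir <- withr::local_tempdir()
  write_grid_summary(s, dir)
  tab <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(tab), 2)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_length(js, 2)
})
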