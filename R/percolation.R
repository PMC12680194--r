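# Newman-Ziff union-find percolation and robustness summaries.
#
# All curves and summary measures are computed on the microcanonical
# occupation-number grid: after adding n of the M edges (or n of the N
# nodes), with p = n/M (or n/N). Removal and addition are mirror images: a
# removal process that deletes elements in some order corresponds to adding
# them in the reverse order, which is what the union-find method sweeps.

MODE_CODES <- c(random_edge = 0L, random_node = 1L, targeted_degree = 2L)

#' Build a removal plan
#'
#' The plan stores the ADDITION order (the reverse of the removal order).
#' Random modes use a uniform permutation of the edges or nodes. The
#' targeted mode removes nodes by decreasing INITIAL degree (static order,
#' as required for a fixed Newman-Ziff addition sequence), so the stored
#' addition order is by nondecreasing initial degree; ties are broken
#' uniformly at random.
#'
#' @param g an undirected simple igraph object.
#' @param mode one of `"random_edge"`, `"random_node"`, `"targeted_degree"`.
#' @param seed optional integer seed.
#' @return an object of class `"removal_plan"`.
#' @export
make_removal_plan <- function(g, mode = c("random_edge", "random_node",
                                          "targeted_degree"),
                              seed = NULL) {
  check_graph(g)
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  addition <- switch(mode,
    random_edge = sample.int(m),
    random_node = sample.int(n),
    targeted_degree = {
      deg <- igraph::degree(g)
      order(deg, sample.int(n))   # nondecreasing degree, uniform tie-break
    })
  structure(list(mode = mode, addition_order = addition, n = n, m = m),
            class = "removal_plan")
}

#' Largest-component trajectory of one percolation run
#'
#' Incremental union-find addition following the plan. Edge mode: after
#' adding n edges, the largest component is taken among all N (always
#' present) nodes, so the value at n = 0 is 1. Node modes: after adding n
#' nodes only edges with both endpoints present are active and the value at
#' n = 0 is 0. The sequence is always nondecreasing.
#'
#' @param g an undirected simple igraph object.
#' @param plan a `"removal_plan"` for `g`.
#' @return integer vector of largest-component sizes, length M+1 (edge mode)
#'   or N+1 (node modes), indexed by occupation number 0..M or 0..N.
#' @export
newman_ziff_run <- function(g, plan) {
  check_graph(g)
  stopifnot(inherits(plan, "removal_plan"))
  if (plan$n != igraph::vcount(g) || plan$m != igraph::ecount(g))
    stop("plan does not match the graph")
  mode <- if (plan$mode == "random_edge") 0L else 1L
  cpp_newman_ziff(igraph::vcount(g), as_edge_matrix(g),
                  as.integer(plan$addition_order) - 1L, mode)
}

#' Ensemble percolation curves
#'
#' Accumulates the first and second moments of the largest-component size at
#' each occupation number over `n_runs` independent removal plans, and
#' the susceptibility
#' \deqn{\chi = (\langle N_{LCC}^2 \rangle - \langle N_{LCC} \rangle^2) /
#'       \langle N_{LCC} \rangle,}
#' reported as 0 where the mean is 0 (node modes at n = 0).
#'
#' @param g an undirected simple igraph object.
#' @param mode removal mode, see [make_removal_plan()].
#' @param n_runs number of independent runs (chi is meaningful for
#'   `n_runs >= 2`).
#' @param seed optional integer seed.
#' @return an object of class `"percolation_curve"`: list with `mode`,
#'   `n`, `m`, `n_runs`, `occupied` (0..grid), `p`, `mean_lcc`,
#'   `second_moment_lcc`, `chi`.
#' @export
ensemble_curves <- function(g, mode = c("random_edge", "random_node",
                                        "targeted_degree"),
                            n_runs = 100, seed = NULL) {
  check_graph(g)
  mode <- match.arg(mode)
  if (n_runs < 1) stop("`n_runs` must be at least 1")
  if (!is.null(seed)) withr::local_seed(seed)
  res <- cpp_percolation_ensemble(igraph::vcount(g), as_edge_matrix(g),
                                  MODE_CODES[[mode]], as.integer(n_runs))
  mean_lcc <- res$sum_lcc / n_runs
  m2 <- res$sum_lcc2 / n_runs
  chi <- ifelse(mean_lcc > 0, (m2 - mean_lcc^2) / mean_lcc, 0)
  chi <- pmax(chi, 0)   # guard tiny negative rounding
  denom <- if (mode == "random_edge") igraph::ecount(g) else igraph::vcount(g)
  occupied <- seq_len(res$grid) - 1L
  structure(list(mode = mode, n = igraph::vcount(g), m = igraph::ecount(g),
                 n_runs = n_runs, occupied = occupied,
                 p = occupied / denom, mean_lcc = mean_lcc,
                 second_moment_lcc = m2, chi = chi),
            class = "percolation_curve")
}

#' Threshold-based robustness f_x
#'
#' `p_x` is the largest grid retention fraction at which the mean largest
#' component is still below `x * N` (the supremum over the grid), and
#' `f_x = 1 - p_x` is the fraction of removals the network withstands before
#' collapse. When the condition holds nowhere on the grid (e.g. `x * N <= 1`
#' under edge removal, where a single node always remains), the convention
#' is `p_x = 0`, `f_x = 1`.
#'
#' @param curve a `"percolation_curve"`.
#' @param x component-size threshold as a fraction of N (default 0.01).
#' @return list with `p_x`, `f_x` and `x`.
#' @export
f_threshold <- function(curve, x = 0.01) {
  stopifnot(inherits(curve, "percolation_curve"))
  below <- curve$mean_lcc < x * curve$n
  p_x <- if (any(below)) max(curve$p[below]) else 0
  list(p_x = p_x, f_x = 1 - p_x, x = x)
}

#' Schneider robustness R
#'
#' The area under the relative giant-component curve S(p) = N_LCC / N over
#' the full retention range, computed as the uniform average of S over the
#' occupation-number grid. For binomial occupancy this equals the exact
#' integral of E\[S(p)\] over p in \[0, 1\].
#'
#' @param curve a `"percolation_curve"`.
#' @return the robustness value (in \[1/N, 1\] for edge mode).
#' @export
robustness_R <- function(curve) {
  stopifnot(inherits(curve, "percolation_curve"))
  mean(curve$mean_lcc / curve$n)
}

#' Susceptibility peaks
#'
#' Local maxima of the susceptibility over the occupation grid, after
#' optional moving-average smoothing. Grid points where the mean largest
#' component is 0 are excluded from the search. A grid point is a peak when
#' its (smoothed) chi exceeds both neighbours. Multiple peaks indicate
#' multiple percolation transitions (e.g. core and periphery collapsing at
#' different retention levels).
#'
#' @param curve a `"percolation_curve"` accumulated over at least 2 runs.
#' @param window odd moving-average window (default 1 = no smoothing).
#' @return data frame with columns `p_star`, `chi_star`, `f_star`
#'   (`= 1 - p_star`), sorted by `p_star`.
#' @export
susceptibility_peaks <- function(curve, window = 1) {
  stopifnot(inherits(curve, "percolation_curve"))
  if (curve$n_runs < 2)
    stop("susceptibility peaks require at least 2 runs")
  keep <- curve$mean_lcc > 0
  p <- curve$p[keep]
  chi <- curve$chi[keep]
  if (length(chi) < 3) stop("fewer than 3 usable grid points")
  if (window > 1) {
    sm <- stats::filter(chi, rep(1 / window, window), sides = 2)
    chi <- ifelse(is.na(sm), chi, as.numeric(sm))
  }
  i <- 2:(length(chi) - 1)
  is_peak <- chi[i] > chi[i - 1] & chi[i] > chi[i + 1]
  idx <- i[is_peak]
  out <- data.frame(p_star = p[idx], chi_star = chi[idx],
                    f_star = 1 - p[idx])
  out[order(out$p_star), , drop = FALSE]
}

#' Robustness summary of a percolation curve
#'
#' Bundles the threshold measure f_x, the Schneider area R and the
#' susceptibility peak positions.
#'
#' @param curve a `"percolation_curve"`.
#' @param x threshold fraction for [f_threshold()].
#' @param window smoothing window for [susceptibility_peaks()].
#' @return an object of class `"robustness_summary"`.
#' @export
robustness_summary <- function(curve, x = 0.01, window = 1) {
  ft <- f_threshold(curve, x)
  peaks <- if (curve$n_runs >= 2)
    susceptibility_peaks(curve, window)
  else
    data.frame(p_star = numeric(), chi_star = numeric(),
               f_star = numeric())
  structure(list(mode = curve$mode, x = x, p_x = ft$p_x, f_x = ft$f_x,
                 R = robustness_R(curve), peaks = peaks,
                 n_runs = curve$n_runs),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat("Robustness summary (", x$mode, ", ", x$n_runs, " runs)\n", sep = "")
  cat(sprintf("  f_%g%% = %.4f  (p_%g%% = %.4f)\n", 100 * x$x, x$f_x,
              100 * x$x, x$p_x))
  cat(sprintf("  R = %.4f\n", x$R))
  if (nrow(x$peaks)) {
    top <- x$peaks[order(-x$peaks$chi_star), , drop = FALSE]
    top <- utils::head(top, 5)
    top <- top[order(top$p_star), , drop = FALSE]
    cat(sprintf("  %d susceptibility peak(s); highest at p* = %s\n",
                nrow(x$peaks),
                paste(signif(top$p_star, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Write a percolation curve as CSV
#'
#' Columns `n`, `p`, `mean_lcc`, `second_moment_lcc`, `chi`.
#' @param curve a `"percolation_curve"`.
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "percolation_curve"))
  utils::write.csv(data.frame(n = curve$occupied, p = curve$p,
                              mean_lcc = curve$mean_lcc,
                              second_moment_lcc = curve$second_moment_lcc,
                              chi = curve$chi),
                   path, row.names = FALSE)
  invisible(path)
}
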