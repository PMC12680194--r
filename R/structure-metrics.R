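# Structural metrics: k-core profile, network efficiency, diameter and the
# Molloy-Reed percolation threshold.

#' k-core size profile
#'
#' For each k >= 1, the number of nodes in the k-core: the maximal subgraph
#' in which every node has at least k neighbours within the subgraph
#' (standard iterative pruning). The profile is nonincreasing in k and the
#' (k+1)-core node set is nested inside the k-core.
#'
#' @param g an undirected simple igraph object.
#' @return data frame with columns `k` and `size`, for k = 1..max coreness
#'   (zero rows when the graph has no edges).
#' @export
k_core_profile <- function(g) {
  check_graph(g)
  cores <- igraph::coreness(g)
  kmax <- if (length(cores)) max(cores) else 0L
  if (kmax < 1) return(data.frame(k = integer(), size = integer()))
  ks <- seq_len(kmax)
  data.frame(k = ks,
             size = vapply(ks, function(k) sum(cores >= k), integer(1)))
}

#' Network efficiency over connected pairs
#'
#' The mean of the inverse shortest-path length over ordered node pairs
#' (i, j), i != j, that are CONNECTED (finite distance). Note this averages
#' over connected pairs only -- disconnected pairs are excluded rather than
#' contributing 0 as in the common global-efficiency convention; set
#' `all_pairs = TRUE` for the latter. Also reports the diameter `l_max`, the
#' largest finite shortest-path distance over the scanned pairs.
#'
#' For large graphs a uniform sample of BFS source nodes can be used; the
#' estimator averages the per-source efficiencies over the sampled sources.
#'
#' @param g an undirected simple igraph object with at least one edge.
#' @param sample_sources number of uniformly sampled BFS sources, or `NULL`
#'   (all nodes, exact).
#' @param all_pairs average over all ordered pairs with 1/infinity = 0
#'   instead of connected pairs only.
#' @param seed optional integer seed for source sampling.
#' @return an object of class `"efficiency_summary"`: list with `E`,
#'   `n_pairs` (ordered pairs used), `l_max` and `sampled`.
#' @export
#' @examples
#' efficiency(fixture_graph("path_3"))  # (1 + 1 + 1/2)/3 = 5/6
efficiency <- function(g, sample_sources = NULL, all_pairs = FALSE,
                       seed = NULL) {
  check_graph(g)
  if (igraph::ecount(g) == 0) stop("efficiency undefined: graph has no edges")
  n <- igraph::vcount(g)
  sources <- if (is.null(sample_sources)) {
    seq_len(n)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    sample.int(n, min(sample_sources, n))
  }
  d <- igraph::distances(g, v = sources, algorithm = "unweighted")
  d <- d[, , drop = FALSE]
  self <- cbind(seq_along(sources), sources)
  d[self] <- Inf   # exclude i = j
  finite <- is.finite(d)
  if (!any(finite)) stop("efficiency undefined: no connected pairs")
  E <- if (all_pairs) {
    sum(1 / d[finite]) / (length(sources) * (n - 1))
  } else {
    mean(1 / d[finite])
  }
  structure(list(E = E, n_pairs = sum(finite), l_max = max(d[finite]),
                 sampled = !is.null(sample_sources)),
            class = "efficiency_summary")
}

#' Efficiency under random removal
#'
#' Monte-Carlo estimate of the efficiency E(p) of the graph surviving after
#' a fraction 1-p of edges or nodes is removed (p is the RETENTION
#' fraction). Removal matches the percolation modes: uniform edges, uniform
#' nodes, or nodes by decreasing initial degree (uniform tie-break).
#' Efficiency is computed among surviving nodes over connected pairs; grid
#' entries where no connected pair survives in any run are `NA`.
#'
#' @param g an undirected simple igraph object.
#' @param mode removal mode, see [make_removal_plan()].
#' @param p_grid retention fractions (default 0.05..1 in steps of 0.05).
#' @param n_runs Monte-Carlo runs per grid point (default 10).
#' @param seed optional integer seed.
#' @return data frame with columns `p`, `efficiency` (mean over runs with at
#'   least one connected pair) and `n_ok` (number of such runs).
#' @export
efficiency_under_removal <- function(g, mode = c("random_edge",
                                                 "random_node",
                                                 "targeted_degree"),
                                     p_grid = seq(0.05, 1, by = 0.05),
                                     n_runs = 10, seed = NULL) {
  check_graph(g)
  mode <- match.arg(mode)
  if (any(p_grid < 0 | p_grid > 1)) stop("`p_grid` must lie in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  one_run <- function(p) {
    surv <- if (mode == "random_edge") {
      keep <- sample.int(m, round(p * m))
      igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    } else {
      n_keep <- round(p * n)
      keep <- if (mode == "random_node") {
        sample.int(n, n_keep)
      } else {
        deg <- igraph::degree(g)
        order(deg, sample.int(n))[seq_len(n_keep)]   # lowest degrees survive
      }
      igraph::induced_subgraph(g, keep)
    }
    tryCatch(efficiency(surv)$E, error = function(e) NA_real_)
  }
  rows <- lapply(p_grid, function(p) {
    es <- vapply(seq_len(n_runs), function(i) one_run(p), numeric(1))
    ok <- !is.na(es)
    data.frame(p = p,
               efficiency = if (any(ok)) mean(es[ok]) else NA_real_,
               n_ok = sum(ok))
  })
  do.call(rbind, rows)
}

#' Molloy-Reed percolation threshold
#'
#' The bond/site percolation threshold of an uncorrelated random network,
#' `p_c = <k> / (<k^2> - <k>)`, from either a realized degree sequence
#' (sample moments) or an analytic degree distribution given as support `k`
#' and probabilities `pk` (normalized internally).
#'
#' @param degrees integer degree sequence (mutually exclusive with
#'   `k`/`pk`).
#' @param k,pk support and probabilities of a degree distribution.
#' @return the threshold `p_c`. Errors when `<k^2> <= <k>` (criterion
#'   undefined; the network has no giant component to destroy).
#' @export
#' @examples
#' molloy_reed_threshold(degrees = rep(3, 10))           # 3/(9-3) = 0.5
#' tp <- truncated_powerlaw(2.5, 2, 141)
#' molloy_reed_threshold(k = tp$k, pk = tp$pk)           # ~0.07
molloy_reed_threshold <- function(degrees = NULL, k = NULL, pk = NULL) {
  if (!is.null(degrees)) {
    if (!is.null(k) || !is.null(pk))
      stop("give either `degrees` or `k`/`pk`, not both")
    m1 <- mean(degrees)
    m2 <- mean(degrees^2)
  } else {
    if (is.null(k) || is.null(pk)) stop("need `degrees` or both `k` and `pk`")
    pk <- pk / sum(pk)
    m1 <- sum(k * pk)
    m2 <- sum(k^2 * pk)
  }
  if (m2 <= m1)
    stop("Molloy-Reed criterion undefined: <k^2> <= <k>")
  m1 / (m2 - m1)
}

#' @export
print.efficiency_summary <- function(x, ...) {
  cat(sprintf("Efficiency E = %.4f over %d connected ordered pairs%s; l_max = %d\n",
              x$E, x$n_pairs, if (x$sampled) " (sampled sources)" else "",
              as.integer(x$l_max)))
  invisible(x)
}
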