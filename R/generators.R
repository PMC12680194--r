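# Initial-network generators: Erdos-Renyi G(N, M), the truncated power-law
# configuration model with structural cutoff, and deterministic toy fixtures.

#' Erdos-Renyi random graph with fixed edge count
#'
#' G(N, M) with `M = round(N * mean_degree / 2)` distinct uniformly chosen
#' edges, so the mean degree is controlled exactly. For large N the degree
#' distribution approximates Poisson(`mean_degree`).
#'
#' @param n number of nodes (>= 2).
#' @param mean_degree target mean degree.
#' @param seed optional integer seed; the same seed yields the identical
#'   graph.
#' @return an undirected simple igraph object.
#' @export
erdos_renyi_graph <- function(n, mean_degree, seed = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  m <- round(n * mean_degree / 2)
  if (m > n * (n - 1) / 2) stop("infeasible edge count for a simple graph")
  if (!is.null(seed)) withr::local_seed(seed)
  igraph::sample_gnm(n, m)
}

#' Truncated power-law degree distribution
#'
#' The normalized pmf P(k) proportional to k^(-gamma) on the integer support
#' `k_min..k_c`, together with its first two moments (computed by direct
#' summation).
#'
#' @param gamma power-law exponent (> 1).
#' @param k_min minimum degree.
#' @param k_c maximum (cutoff) degree.
#' @return list with `k`, `pk`, `mean`, `second_moment`.
#' @export
truncated_powerlaw <- function(gamma, k_min, k_c) {
  if (gamma <= 1) stop("`gamma` must exceed 1")
  if (k_min < 1 || k_c < k_min) stop("need 1 <= k_min <= k_c")
  k <- k_min:k_c
  pk <- k^(-gamma)
  pk <- pk / sum(pk)
  list(k = k, pk = pk, mean = sum(k * pk), second_moment = sum(k^2 * pk))
}

#' Power-law configuration model with structural cutoff
#'
#' Draws an i.i.d. degree sequence from the truncated power law
#' P(k) proportional to k^(-gamma) on `k_min..k_c` by inverse-CDF sampling on
#' the integer support (with a parity fix: while the degree sum is odd, one
#' uniformly chosen node's degree is redrawn). Uniform stub matching is
#' followed by removal of self-loops and multi-edges via degree-preserving
#' double-edge swaps against uniformly chosen partner edges, so the realized
#' degree sequence equals the drawn one exactly.
#'
#' The default cutoff is the structural cutoff `floor(sqrt(n))`, above which
#' an uncorrelated simple graph cannot avoid induced degree correlations.
#'
#' @param n number of nodes.
#' @param gamma power-law exponent.
#' @param k_min minimum degree.
#' @param k_c maximum degree; defaults to `floor(sqrt(n))`.
#' @param seed optional integer seed.
#' @return an undirected simple igraph object whose degrees all lie in
#'   `[k_min, k_c]`.
#' @export
powerlaw_configuration_graph <- function(n, gamma = 2.5, k_min = 2,
                                         k_c = NULL, seed = NULL) {
  if (is.null(k_c)) k_c <- floor(sqrt(n))
  if (k_c > n - 1) stop("`k_c` must be at most n - 1")
  dist <- truncated_powerlaw(gamma, k_min, k_c)
  if (!is.null(seed)) withr::local_seed(seed)
  cdf <- cumsum(dist$pk)
  draw <- function(nd)
    dist$k[findInterval(stats::runif(nd), cdf, rightmost.closed = TRUE) + 1L]
  deg <- draw(n)
  while (sum(deg) %% 2 == 1) {
    i <- sample.int(n, 1)
    deg[i] <- draw(1)
  }
  stubs <- rep.int(seq_len(n), deg)
  stubs <- sample(stubs)
  edges <- matrix(stubs, ncol = 2, byrow = TRUE)
  m <- nrow(edges)
  edges0 <- cpp_simplify_by_swaps(n, edges - 1L,
                                  max_attempts = 1e6 + 200 * m)
  g <- graph_from_edge_matrix(edges0, n)
  stopifnot(identical(as.integer(igraph::degree(g)), as.integer(deg)))
  g
}

#' Deterministic toy graphs
#'
#' Named fixtures used throughout the tests and examples: `"path_n"`,
#' `"star_n"` (one centre, n-1 leaves), `"cycle_n"`, `"clique_n"`, where the
#' trailing integer is the total node count, e.g. `"path_4"` or
#' `"clique_4"`.
#'
#' @param name fixture name.
#' @return an undirected simple igraph object.
#' @export
fixture_graph <- function(name) {
  m <- regmatches(name, regexec("^(path|star|cycle|clique)_([0-9]+)$", name))[[1]]
  if (length(m) == 0) stop("unknown fixture name: ", name)
  n <- as.integer(m[3])
  switch(m[2],
         path = igraph::make_ring(n, circular = FALSE),
         star = igraph::make_star(n, mode = "undirected", center = 1),
         cycle = igraph::make_ring(n, circular = TRUE),
         clique = igraph::make_full_graph(n))
}
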