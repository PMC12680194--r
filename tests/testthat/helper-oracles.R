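# Independent oracles used across the test files. These deliberately avoid
# the package's own C++ kernels: correlations are recomputed from
# igraph::distances() + stats::cor(), and percolation expectations from
# exhaustive subset enumeration.

# Pearson degree-degree correlation at exact shortest-path distance l,
# over ordered node pairs. Returns NA (from cor) when a marginal has zero
# variance, and NULL when there are no pairs at distance l.
oracle_r_at_distance <- function(g, l) {
  d <- igraph::distances(g, algorithm = "unweighted")
  deg <- igraph::degree(g)
  idx <- which(d == l, arr.ind = TRUE)   # ordered pairs, both directions
  if (nrow(idx) == 0) return(NULL)
  suppressWarnings(stats::cor(deg[idx[, 1]], deg[idx[, 2]]))
}

# Number of unordered node pairs at exact distance l.
oracle_pair_count <- function(g, l) {
  d <- igraph::distances(g, algorithm = "unweighted")
  sum(d == l) / 2
}

# Exact microcanonical bond-percolation curve by exhaustive enumeration:
# element k of the returned list (k = 0..M) gives the vector of
# largest-component sizes over all edge subsets of size k (all N nodes
# always present).
oracle_edge_percolation_sets <- function(g) {
  m <- igraph::ecount(g)
  lapply(0:m, function(k) {
    subs <- utils::combn(seq_len(m), k)
    apply(subs, 2, function(s) {
      sg <- igraph::subgraph_from_edges(g, s, delete.vertices = FALSE)
      max(igraph::components(sg)$csize)
    })
  })
}

# Same for site percolation: all node subsets of size k (k = 0..N); an
# empty subset contributes 0.
oracle_node_percolation_sets <- function(g) {
  n <- igraph::vcount(g)
  lapply(0:n, function(k) {
    if (k == 0) return(0)
    subs <- utils::combn(seq_len(n), k)
    apply(subs, 2, function(s) {
      cs <- igraph::components(igraph::induced_subgraph(g, s))$csize
      if (length(cs)) max(cs) else 0L
    })
  })
}

# Compare a simulated ensemble curve against enumerated subset values:
# each grid point must lie within `n_se` standard errors of the exact
# microcanonical mean (exact equality where the enumerated variance is 0).
expect_curve_matches_enumeration <- function(curve, sets, n_se = 5) {
  exact_mean <- vapply(sets, mean, numeric(1))
  exact_var <- vapply(sets, function(x) mean(x^2) - mean(x)^2, numeric(1))
  se <- sqrt(exact_var / curve$n_runs)
  tol <- ifelse(se > 0, n_se * se, 1e-12)
  expect_true(all(abs(curve$mean_lcc - exact_mean) <= tol),
              label = sprintf("curve within %d SE of enumeration", n_se))
}

# Small test graphs used repeatedly.
path4 <- function() fixture_graph("path_4")
star4 <- function() fixture_graph("star_4")   # K1,3, center is node 1
cycle5 <- function() fixture_graph("cycle_5")

# The two labeled simple graphs on degrees (1, 1, 2, 2): a path with interior
# nodes {3, 4} (used as the chain's start state) and its unique swap partner.
two_state_start <- function() {
  igraph::make_graph(c(1, 3, 3, 4, 4, 2), n = 4, directed = FALSE)
}
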