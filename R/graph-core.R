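# Graph plumbing around igraph: validation, 0-based edge matrices for the
# compiled kernels, exact-distance queries, double-edge swaps, and file IO.

#' Validate an undirected simple graph
#'
#' @param g an igraph object.
#' @return `g`, invisibly, after checking it is undirected and simple.
#' @keywords internal
check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object")
  if (igraph::is_directed(g)) stop("`g` must be undirected")
  if (!igraph::is_simple(g)) stop("`g` must be simple (no loops/multi-edges)")
  invisible(g)
}

#' 0-based integer edge matrix of a graph
#'
#' @param g an undirected simple igraph object.
#' @return integer matrix with one row per edge, 0-based node ids.
#' @keywords internal
as_edge_matrix <- function(g) {
  check_graph(g)
  m <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(m) <- "integer"
  m - 1L
}

#' Build an igraph from a 0-based edge matrix
#' @keywords internal
graph_from_edge_matrix <- function(edges, n) {
  igraph::make_graph(edges = as.vector(t(edges + 1L)), n = n,
                     directed = FALSE)
}

#' Nodes at an exact shortest-path distance
#'
#' Returns the set of nodes whose unweighted shortest-path distance from `v`
#' is exactly `l` (the BFS frontier at depth `l`). Nodes in other components
#' never appear; `l = 0` returns `v` itself.
#'
#' @param g an undirected simple igraph object.
#' @param v a node id (1-based vertex index).
#' @param l nonnegative integer distance.
#' @return integer vector of node ids.
#' @export
#' @examples
#' g <- fixture_graph("path_4")
#' neighbors_at_distance(g, 1, 2)  # the single node two steps along
neighbors_at_distance <- function(g, v, l) {
  check_graph(g)
  n <- igraph::vcount(g)
  v <- as.integer(v)
  if (length(v) != 1 || is.na(v) || v < 1 || v > n)
    stop("unknown node id: ", v)
  if (l < 0) stop("`l` must be nonnegative")
  out <- cpp_neighbors_at_distance(n, as_edge_matrix(g), v - 1L,
                                   as.integer(l))
  out + 1L
}

#' All node pairs at an exact shortest-path distance
#'
#' Enumerates every unordered pair \{i, j\} with shortest-path distance
#' exactly `l`. Each pair appears once regardless of how many shortest paths
#' connect it; pairs in different components are excluded. `M(l)` is the
#' number of such pairs, so `distance_pairs(g, 1)` returns exactly the edge
#' set.
#'
#' @param g an undirected simple igraph object.
#' @param l positive integer distance.
#' @return list with `pairs` (two-column matrix of 1-based node ids, i < j)
#'   and `m_l` (the pair count M(l)).
#' @export
distance_pairs <- function(g, l) {
  check_graph(g)
  if (l < 1) stop("`l` must be a positive integer")
  p <- cpp_distance_pairs(igraph::vcount(g), as_edge_matrix(g),
                          as.integer(l)) + 1L
  list(pairs = p, m_l = nrow(p))
}

#' Degree-preserving double-edge swap
#'
#' Attempts to replace the (oriented) edges `(u1,u2)` and `(v1,v2)` by
#' `(u1,v2)` and `(v1,u2)`. All node degrees are unchanged by construction.
#' The proposal is rejected -- leaving the graph unmodified -- when it would
#' create a self-loop or a multi-edge, or when the replacement equals the
#' current edge set (a no-op, e.g. when the two edges share their source).
#'
#' @param g an undirected simple igraph object.
#' @param e1,e2 length-2 vectors of node ids giving the two ordered edges;
#'   both must be current edges of `g` (an error otherwise, distinct from
#'   rejection).
#' @return list with `applied` (logical), `graph` (the swapped graph if
#'   applied, otherwise `g`), and `reason` (`NA` if applied, else one of
#'   `"self-loop"`, `"multi-edge"`, `"no-op"`).
#' @export
swap_edges <- function(g, e1, e2) {
  check_graph(g)
  u1 <- as.integer(e1[1]); u2 <- as.integer(e1[2])
  v1 <- as.integer(e2[1]); v2 <- as.integer(e2[2])
  if (!igraph::are_adjacent(g, u1, u2))
    stop("e1 is not an edge of the graph")
  if (!igraph::are_adjacent(g, v1, v2))
    stop("e2 is not an edge of the graph")
  reject <- function(reason)
    list(applied = FALSE, graph = g, reason = reason)
  same_edge <- identical(sort(c(u1, u2)), sort(c(v1, v2)))
  if (same_edge || u1 == v1 || u2 == v2) return(reject("no-op"))
  if (u1 == v2 || v1 == u2) return(reject("self-loop"))
  if (igraph::are_adjacent(g, u1, v2) || igraph::are_adjacent(g, v1, u2))
    return(reject("multi-edge"))
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
    g, c(u1, u2, v1, v2)))
  g2 <- igraph::add_edges(g2, c(u1, v2, v1, u2))
  list(applied = TRUE, graph = g2, reason = NA_character_)
}

#' Read an undirected edge list
#'
#' Two whitespace-separated integer node labels per line; `#` starts a
#' comment. Arbitrary integer labels are relabelled to contiguous 1..N ids;
#' the original labels are kept in the vertex attribute `"label"`.
#'
#' @param path file path.
#' @return an undirected simple igraph object.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           colClasses = "integer",
                           col.names = c("from", "to"))
  labels <- sort(unique(c(tab$from, tab$to)))
  from <- match(tab$from, labels)
  to <- match(tab$to, labels)
  g <- igraph::make_graph(edges = as.vector(rbind(from, to)),
                          n = length(labels), directed = FALSE)
  igraph::V(g)$label <- labels
  check_graph(g)
  g
}

#' Write an undirected edge list
#'
#' Each edge is written once, using the `"label"` vertex attribute when
#' present and 1-based ids otherwise.
#'
#' @param g an undirected simple igraph object.
#' @param path file path.
#' @export
write_edgelist <- function(g, path) {
  check_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  labels <- igraph::vertex_attr(g, "label")
  if (!is.null(labels)) {
    el[, 1] <- labels[el[, 1]]
    el[, 2] <- labels[el[, 2]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# undirected edge list (one edge per line)", con)
  writeLines(paste(el[, 1], el[, 2]), con)
  invisible(path)
}

#' Read a GraphML file as an undirected simple graph
#' @param path file path.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  check_graph(g)
  g
}

#' Write a graph to GraphML
#' @param g an igraph object.
#' @param path file path.
#' @export
write_graphml <- function(g, path) {
  check_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
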