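#' Cached clustering state of an undirected network
#'
#' Builds the bookkeeping needed to update the clustering coefficient in
#' (near) constant time after a link insertion: per-node degree `d_v`,
#' per-node triangle count `T(v)`, the local clustering coefficients
#' `C(v) = 2 T(v) / (d_v (d_v - 1))` (zero when `d_v <= 1`), and the network
#' clustering coefficient `C_G`, the arithmetic mean of `C(v)` over all
#' nodes (the Watts-Strogatz average).
#'
#' The input must be a simple, loopless, undirected graph with at least one
#' node. Vertices without a `name` attribute are labelled `"1"`, `"2"`, ...
#' in vertex order.
#'
#' @param graph An [igraph::igraph] object, undirected, simple and loopless.
#' @return An object of class `clustering_state`: a list with elements
#'   `graph` (the igraph object), `labels` (character vertex names), `adj`
#'   (dense 0/1 adjacency matrix), `deg`, `tri` (named integer vectors),
#'   `local` (named numeric vector of `C(v)`), `C` (the scalar `C_G`) and
#'   `n` (node count).
#' @examples
#' st <- clustering_state(example_graph())
#' st$C # 7/24
#' @seealso [graph_clustering()], [updated_graph_clustering()], [apply_link()]
#' @export
clustering_state <- function(graph) {
  check_simple_graph(graph)
  graph <- ensure_names(graph)
  labels <- igraph::V(graph)$name
  n <- length(labels)
  adj <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  storage.mode(adj) <- "double"
  dimnames(adj) <- list(labels, labels)
  deg <- igraph::degree(graph)
  tri <- igraph::count_triangles(graph)
  names(deg) <- names(tri) <- labels
  local <- local_clustering(deg, tri)
  structure(
    list(graph = graph, labels = labels, adj = adj, deg = deg, tri = tri,
         local = local, C = mean(local), n = n),
    class = "clustering_state"
  )
}

#' @export
print.clustering_state <- function(x, ...) {
  cat("<clustering_state> ", x$n, " nodes, ",
      igraph::ecount(x$graph), " links, C_G = ",
      format(x$C, digits = 6), "\n", sep = "")
  invisible(x)
}

local_clustering <- function(deg, tri) {
  ifelse(deg > 1, 2 * tri / (deg * (deg - 1)), 0)
}

ensure_names <- function(graph) {
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

check_simple_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    abort("`graph` must be an igraph object.", class = "clustlink_type_error")
  }
  if (igraph::is_directed(graph)) {
    abort("`graph` must be undirected.", class = "clustlink_type_error")
  }
  if (igraph::vcount(graph) < 1) {
    abort("`graph` must have at least one node.", class = "clustlink_domain_error")
  }
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    abort("`graph` must be simple: no self-loops or duplicate links.",
          class = "clustlink_domain_error")
  }
  invisible(graph)
}

as_clustering_state <- function(x) {
  if (inherits(x, "clustering_state")) x else clustering_state(x)
}

check_node <- function(state, v, arg = "v") {
  if (length(v) != 1 || !v %in% state$labels) {
    abort(paste0("`", arg, "` must name a single node of the graph."),
          class = "clustlink_identifier_error")
  }
  invisible(v)
}

#' Local clustering coefficient of a node
#'
#' `C(v) = 2 T(v) / (d_v (d_v - 1))` for degree `d_v > 1`, and 0 for
#' isolated or degree-1 nodes: the fraction of links present among the
#' neighbours of `v`.
#'
#' @param x A graph or a [clustering_state()].
#' @param v Node label.
#' @return A proportion in `[0, 1]`.
#' @examples
#' node_clustering(example_graph(), "w") # 1/3
#' @export
node_clustering <- function(x, v) {
  state <- as_clustering_state(x)
  check_node(state, v)
  unname(state$local[v])
}

#' Clustering coefficient of a network
#'
#' The Watts-Strogatz network clustering coefficient: the arithmetic mean of
#' the local clustering coefficients over all `n` nodes.
#'
#' @inheritParams node_clustering
#' @return A proportion in `[0, 1]`.
#' @examples
#' graph_clustering(example_graph()) # 7/24
#' @export
graph_clustering <- function(x) {
  as_clustering_state(x)$C
}

#' Per-node triangle counts
#'
#' `T(v)` is the number of links among the neighbours of `v`, i.e. the number
#' of triangles `v` belongs to; each triangle contributes 1 to each of its
#' three corners.
#'
#' @inheritParams node_clustering
#' @return A named integer vector over nodes.
#' @export
triangle_counts <- function(x) {
  as_clustering_state(x)$tri
}

#' Common neighbours of two nodes
#'
#' `N(u, v)`: the nodes adjacent to both `u` and `v`. Its size `k` drives the
#' change of the clustering coefficient when the link `(u, v)` is inserted.
#'
#' @inheritParams node_clustering
#' @param u,v Distinct node labels.
#' @return Character vector of node labels (possibly empty).
#' @examples
#' common_neighbours(example_graph(), "u", "v") # "e"
#' @export
common_neighbours <- function(x, u, v) {
  state <- as_clustering_state(x)
  check_node(state, u, "u")
  check_node(state, v, "v")
  if (u == v) {
    abort("`u` and `v` must be distinct nodes.", class = "clustlink_domain_error")
  }
  state$labels[state$adj[u, ] * state$adj[v, ] > 0]
}
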