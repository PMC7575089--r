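#' Candidate links: all missing pairs
#'
#' Enumerates every unordered pair of distinct nodes not already linked —
#' the default pool a link-addition strategy chooses from. Pairs are ordered
#' lexicographically by (sorted) label pair, and that order is the tie-break
#' order used by every optimizer.
#'
#' @param graph An undirected simple igraph object.
#' @return A tibble with character columns `u`, `v` (with `u < v`
#'   lexicographically), classed `candidate_set`, carrying a `provenance`
#'   attribute.
#' @examples
#' nrow(all_missing_links(example_graph())) # 18
#' @export
all_missing_links <- function(graph) {
  state <- as_clustering_state(graph)
  labs <- sort(state$labels)
  if (length(labs) < 2) {
    return(new_candidate_set(tibble(u = character(), v = character()),
                             "all-missing"))
  }
  pairs <- t(combn(labs, 2))
  keep <- state$adj[pairs] == 0  # matrix indexing by label pairs
  new_candidate_set(tibble(u = pairs[keep, 1], v = pairs[keep, 2]),
                    "all-missing")
}

new_candidate_set <- function(tbl, provenance) {
  tbl <- dplyr::arrange(tbl, .data$u, .data$v)
  attr(tbl, "provenance") <- provenance
  class(tbl) <- c("candidate_set", class(tbl))
  tbl
}

#' Candidate links restricted by Euclidean distance
#'
#' Keeps only the missing pairs whose endpoints lie strictly closer than
#' `max_dist` metres — the dispersal-limited candidate pool used for habitat
#' networks, where a species can only bridge gaps up to its dispersal
#' distance (2500 m by default). The boundary is exclusive: a pair exactly
#' `max_dist` apart is not a candidate.
#'
#' @inheritParams all_missing_links
#' @param max_dist Strict upper bound on endpoint distance, in metres.
#' @param x_attr,y_attr Names of the vertex attributes holding metric
#'   coordinates.
#' @return A `candidate_set` tibble with an additional `dist_m` column.
#' @export
distance_restricted_links <- function(graph, max_dist = 2500,
                                      x_attr = "x", y_attr = "y") {
  xs <- igraph::vertex_attr(graph, x_attr)
  ys <- igraph::vertex_attr(graph, y_attr)
  if (is.null(xs) || is.null(ys) || anyNA(xs) || anyNA(ys)) {
    abort("all nodes need metric coordinates for a distance restriction.",
          class = "clustlink_configuration_error")
  }
  graph <- ensure_names(graph)
  names(xs) <- names(ys) <- igraph::V(graph)$name
  cand <- all_missing_links(graph)
  d <- sqrt((xs[cand$u] - xs[cand$v])^2 + (ys[cand$u] - ys[cand$v])^2)
  cand$dist_m <- unname(d)
  out <- cand[d < max_dist, ]
  new_candidate_set(out, sprintf("distance-restricted(<%g m)", max_dist))
}

check_candidates <- function(state, candidates) {
  if (!is.data.frame(candidates) || !all(c("u", "v") %in% names(candidates))) {
    abort("`candidates` must be a candidate set with columns `u` and `v`.",
          class = "clustlink_type_error")
  }
  if (!all(candidates$u %in% state$labels) || !all(candidates$v %in% state$labels)) {
    abort("candidate endpoints must be nodes of the graph.",
          class = "clustlink_identifier_error")
  }
  invisible(candidates)
}
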