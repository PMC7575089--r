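#' Small worked-example network
#'
#' An 8-node, 10-link network handy for illustrating the clustering-update
#' machinery: its clustering coefficient is 7/24, a single optimally placed
#' link raises it to 1/2 (two tied choices exist), and the best pair of links
#' raises it to 5/8.
#'
#' @return An undirected igraph object with named vertices.
#' @examples
#' g <- example_graph()
#' graph_clustering(g)
#' @export
example_graph <- function() {
  igraph::graph_from_edgelist(
    rbind(
      c("a", "b"), c("a", "w"), c("a", "c"), c("b", "u"), c("b", "w"),
      c("u", "e"), c("w", "c"), c("w", "d"), c("e", "v"), c("d", "v")
    ),
    directed = FALSE
  )
}
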