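#' Standard network generator
#'
#' Generates the non-spatial reference ensembles: Erdos-Renyi random
#' (G(n, M)), random regular, and Watts-Strogatz small-world graphs, in a
#' sparse regime targeting about 4% of the possible links or a dense regime
#' targeting about 75%. Family parameters are derived from the target
#' density:
#' * random: `M = round(density * n(n-1)/2)` links;
#' * regular: degree `round(density * (n-1))`, bumped to make `n * degree`
#'   even;
#' * small-world: ring neighbourhood `nei = max(1, round(density*(n-1)/2))`
#'   with rewiring probability `p` (default 0.1); `p = 0` leaves the ring
#'   lattice, a regular graph.
#'
#' @param family `"random"`, `"regular"` or `"small_world"`.
#' @param regime `"sparse"` (4%) or `"dense"` (75%), or override `density`.
#' @param n Node count (the study range is 50 to 111).
#' @param density Target link density; defaults from `regime`.
#' @param p Rewiring probability for the small-world family.
#' @param seed Integer seed.
#' @return A simple undirected igraph with vertex names `"n001"`, ...
#' @export
generate_standard <- function(family = c("random", "regular", "small_world"),
                              regime = c("sparse", "dense"),
                              n = 60, density = NULL, p = 0.1, seed = 1L) {
  family <- match.arg(family)
  regime <- match.arg(regime)
  if (is.null(density)) density <- if (regime == "sparse") 0.04 else 0.75
  if (n < 2) abort("`n` must be at least 2.", class = "clustlink_configuration_error")
  g <- withr::with_seed(seed, switch(family,
    random = igraph::sample_gnm(n, round(density * n * (n - 1) / 2)),
    regular = {
      k <- max(1, round(density * (n - 1)))
      if ((n * k) %% 2 == 1) k <- k + 1
      if (k >= n) abort("regular degree must be below n; lower the density.",
                        class = "clustlink_configuration_error")
      igraph::sample_k_regular(n, k)
    },
    small_world = {
      nei <- max(1, round(density * (n - 1) / 2))
      g <- igraph::sample_smallworld(1, n, nei, p, loops = FALSE, multiple = FALSE)
      igraph::simplify(g)
    }
  ))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

#' Generate an ensemble of networks
#'
#' Draws `count` independent replicates of a generator with per-replicate
#' seeds derived from `base_seed`, and a manifest recording every seed and
#' the realised sizes. Node counts are sampled uniformly from `n_range`
#' unless the generator fixes them itself.
#'
#' @param count Number of networks.
#' @param base_seed Master seed; the whole ensemble is reproducible from it.
#' @param generator Either a function `(n, seed) -> igraph`, or the name of a
#'   standard family passed on to [generate_standard()].
#' @param regime Density regime for standard families.
#' @param n_range Inclusive node-count range sampled per replicate.
#' @param ... Extra arguments for [generate_standard()].
#' @return A list with `graphs` (list of igraphs) and `manifest` (tibble:
#'   id, seed, n, links, density).
#' @export
generate_ensemble <- function(count, base_seed = 1L,
                              generator = "random", regime = "sparse",
                              n_range = c(50, 111), ...) {
  if (count < 1) abort("`count` must be at least 1.", class = "clustlink_domain_error")
  draws <- withr::with_seed(base_seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, count),
    ns = sample(seq(n_range[1], n_range[2]), count, replace = TRUE)
  ))
  gen_fun <- if (is.function(generator)) {
    generator
  } else {
    function(n, seed) generate_standard(generator, regime, n = n, seed = seed, ...)
  }
  graphs <- purrr::map2(draws$ns, draws$seeds, function(n, s) gen_fun(n, s))
  manifest <- purrr::imap(graphs, function(g, i) {
    n <- igraph::vcount(g)
    tibble(id = i, seed = draws$seeds[i], n = n, links = igraph::ecount(g),
           density = igraph::ecount(g) / (n * (n - 1) / 2))
  })
  list(graphs = graphs, manifest = dplyr::bind_rows(manifest))
}
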