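#' Configuration for synthetic landscape-based habitat networks
#'
#' Describes a square landscape tile rasterised into traversal-cost cells,
#' crossed by a dendritic stream skeleton along which habitat patches are
#' allocated. Patches are connected into a network wherever the least-cost
#' path between them stays below a maximum dispersal cost.
#'
#' Costs are per 25 m x 25 m cell: 50 for open agricultural land, with
#' forestry and urban areas more expensive to traverse (150 and 500 by
#' default; only the ordering open < forest < urban matters qualitatively).
#' The maximum dispersal cost defaults to 900 for random, 650 for clustered
#' and 400 for contiguous patch allocation, which keeps link counts
#' comparable across the three allocation regimes.
#'
#' @param allocation Patch allocation regime: `"random"` (uniform along
#'   streams), `"clustered"` (half the patches seed uniformly, the rest land
#'   within `cluster_radius` of an existing patch) or `"contiguous"` (a
#'   smaller seed fraction, hence longer contiguous runs).
#' @param tile_size Tile edge length in metres.
#' @param cell_size Cell edge length in metres.
#' @param costs Named per-cell traversal costs for the three land-use
#'   classes `open`, `forest`, `urban`.
#' @param class_fractions Named area fractions of the three classes
#'   (must sum to 1).
#' @param habitat_fraction Fraction of stream cells that become habitat
#'   patches.
#' @param cluster_radius Radius (metres) within which clustered/contiguous
#'   follow-up patches are placed.
#' @param seed_fraction Fraction of patches placed uniformly before the
#'   radius rule kicks in; defaults 0.5 (clustered) / 0.2 (contiguous).
#' @param max_cost Maximum cumulative dispersal cost for a link; defaults by
#'   allocation regime (900/650/400).
#' @param stream_cells Inclusive range the stream-skeleton cell count is
#'   drawn from; with `habitat_fraction = 0.1` this yields 54 to 111
#'   patches, the size range of the real stream-network tiles the generator
#'   emulates.
#' @param smooth Half-width (cells) of the smoothing window shaping the
#'   land-use mosaic.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(allocation = c("random", "clustered", "contiguous"),
                             tile_size = 10000, cell_size = 25,
                             costs = c(open = 50, forest = 150, urban = 500),
                             class_fractions = c(open = 0.7, forest = 0.2, urban = 0.1),
                             habitat_fraction = 0.1,
                             cluster_radius = 1000,
                             seed_fraction = NULL,
                             max_cost = NULL,
                             stream_cells = c(560, 1100),
                             smooth = 10) {
  allocation <- match.arg(allocation)
  if (is.null(seed_fraction)) {
    seed_fraction <- switch(allocation, random = 1, clustered = 0.5, contiguous = 0.2)
  }
  if (is.null(max_cost)) {
    max_cost <- switch(allocation, random = 900, clustered = 650, contiguous = 400)
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    abort("`class_fractions` must sum to 1.", class = "clustlink_configuration_error")
  }
  if (any(costs <= 0)) {
    abort("all traversal costs must be strictly positive.",
          class = "clustlink_configuration_error")
  }
  structure(
    list(allocation = allocation, tile_size = tile_size, cell_size = cell_size,
         costs = costs, class_fractions = class_fractions,
         habitat_fraction = habitat_fraction, cluster_radius = cluster_radius,
         seed_fraction = seed_fraction, max_cost = max_cost,
         stream_cells = stream_cells, smooth = smooth),
    class = "landscape_config"
  )
}

# circular 1-D running mean along rows then columns; cheap isotropic-ish blur
smooth_matrix <- function(m, half_width) {
  w <- rep(1 / (2 * half_width + 1), 2 * half_width + 1)
  m <- apply(m, 2, function(col) stats::filter(col, w, circular = TRUE))
  t(apply(t(m), 2, function(col) stats::filter(col, w, circular = TRUE)))
}

# Dendritic stream skeleton: a main channel random-walked across the tile,
# plus branches sprouted from random stream cells, all with 8-connected
# steps and directional momentum. Connected by construction.
grow_stream <- function(nr, nc, target_cells) {
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  in_grid <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  stream <- matrix(FALSE, nr, nc)
  cells <- matrix(integer(), 0, 2)
  walk <- function(start, dir_idx, max_len) {
    p <- start
    for (s in seq_len(max_len)) {
      if (runif(1) > 0.85) dir_idx <- 1 + (dir_idx - 1 + sample(c(-1, 1), 1)) %% 8
      p2 <- p + dirs[dir_idx, ]
      if (!in_grid(p2)) break
      p <- p2
      if (!stream[p[1], p[2]]) {
        stream[p[1], p[2]] <<- TRUE
        cells <<- rbind(cells, p)
      }
    }
  }
  start <- c(sample(nr, 1), 1)
  stream[start[1], start[2]] <- TRUE
  cells <- rbind(cells, start)
  walk(start, 3, nc * 3)                      # main channel, west to east
  guard <- 0
  while (nrow(cells) < target_cells && guard < 500) {
    guard <- guard + 1
    from <- cells[sample(nrow(cells), 1), ]
    walk(from, sample(8, 1), sample(60:160, 1))
  }
  stream[] <- FALSE
  stream[cells] <- TRUE
  list(mask = stream, cells = cells[seq_len(min(nrow(cells), target_cells)), , drop = FALSE])
}

#' Synthesize a traversal-cost raster with a stream skeleton
#'
#' Builds a square mosaic of the three land-use classes (by thresholding a
#' smoothed noise field at the configured area fractions) and a connected,
#' tree-like stream skeleton grown by momentum random walks. Stream cells
#' take the open-land cost: the watercourse is the cheap corridor patches
#' sit on.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed.
#' @param n_stream Stream cell count; drawn from `config$stream_cells` when
#'   `NULL`.
#' @return A list of class `cost_raster`: `cost` (numeric matrix),
#'   `stream` (logical matrix), `config`, `cell_size`.
#' @export
synthesize_cost_raster <- function(config, seed = 1L, n_stream = NULL) {
  ncell <- round(config$tile_size / config$cell_size)
  withr::with_seed(seed, {
    if (is.null(n_stream)) {
      n_stream <- sample(seq(config$stream_cells[1], config$stream_cells[2]), 1)
    }
    field <- smooth_matrix(matrix(rnorm(ncell^2), ncell, ncell), config$smooth)
    qs <- stats::quantile(field, cumsum(config$class_fractions)[1:2])
    cls <- matrix("open", ncell, ncell)
    cls[field > qs[1]] <- "forest"
    cls[field > qs[2]] <- "urban"
    cost <- matrix(config$costs[cls], ncell, ncell)
    st <- grow_stream(ncell, ncell, n_stream)
    cost[st$mask] <- config$costs[["open"]]
    structure(list(cost = cost, stream = st$mask, config = config,
                   cell_size = config$cell_size),
              class = "cost_raster")
  })
}

#' Allocate habitat patches along the stream skeleton
#'
#' Selects `habitat_fraction` of the stream cells as habitat patches.
#' Random allocation samples uniformly; clustered and contiguous allocation
#' first place a seed fraction uniformly and then repeatedly pick a uniform
#' stream cell within `cluster_radius` of an already chosen patch, which
#' pulls patches together (contiguous uses a smaller seed fraction, hence
#' longer runs).
#'
#' @param raster A [synthesize_cost_raster()] result.
#' @param config A [landscape_config()]; defaults to the raster's own.
#' @param seed Integer seed.
#' @return A tibble: `label`, `row`, `col`, `x`, `y` (metres, cell centres).
#' @export
allocate_patches <- function(raster, config = raster$config, seed = 1L) {
  stream_idx <- which(raster$stream)
  n_stream <- length(stream_idx)
  n_patch <- round(config$habitat_fraction * n_stream)
  if (n_stream < n_patch || n_patch < 1) {
    abort("not enough stream cells to allocate patches.",
          class = "clustlink_generation_error")
  }
  nr <- nrow(raster$cost)
  rows <- ((stream_idx - 1) %% nr) + 1
  cols <- ((stream_idx - 1) %/% nr) + 1
  xs <- (cols - 0.5) * raster$cell_size
  ys <- (rows - 0.5) * raster$cell_size
  chosen <- withr::with_seed(seed, {
    if (config$allocation == "random" || config$seed_fraction >= 1) {
      sample(n_stream, n_patch)
    } else {
      n_seed <- max(1, round(config$seed_fraction * n_patch))
      sel <- sample(n_stream, n_seed)
      while (length(sel) < n_patch) {
        d2 <- outer(xs, xs[sel], "-")^2 + outer(ys, ys[sel], "-")^2
        near <- which(apply(d2 <= config$cluster_radius^2, 1, any))
        pool <- setdiff(near, sel)
        if (length(pool) == 0) pool <- setdiff(seq_len(n_stream), sel)
        sel <- c(sel, pool[sample.int(length(pool), 1)])
      }
      sel
    }
  })
  chosen <- sort(chosen)
  tibble(label = sprintf("p%03d", seq_along(chosen)),
         row = rows[chosen], col = cols[chosen],
         x = xs[chosen], y = ys[chosen])
}

# 8-connected grid graph over the cost raster; edge weight is the mean of
# the two cell costs (x sqrt(2) for diagonal steps), so a path across k
# uniform-cost cells accumulates ~ k * cost.
grid_graph <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- function(dr, dc) {
    r <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
    c <- seq_len(nc - dc)
    from <- as.vector(outer(r, c, id))
    to <- as.vector(outer(r + dr, c + dc, id))
    w <- (cost[from] + cost[to]) / 2
    if (dr != 0 && dc != 0) w <- w * sqrt(2)
    list(from = from, to = to, w = w)
  }
  e <- list(edges(0, 1), edges(1, 0), edges(1, 1), edges(-1, 1))
  from <- unlist(lapply(e, `[[`, "from"))
  to <- unlist(lapply(e, `[[`, "to"))
  w <- unlist(lapply(e, `[[`, "w"))
  g <- igraph::make_empty_graph(nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Link habitat patches by least-cost paths
#'
#' Computes, for every patch pair, the minimal cumulative traversal cost
#' over 8-connected grid paths (Dijkstra on the cost-weighted grid graph)
#' and inserts a link wherever that cost is strictly below `max_cost`.
#'
#' @param raster A [synthesize_cost_raster()] result (or any list with a
#'   `cost` matrix and `cell_size`).
#' @param patches A patch tibble from [allocate_patches()].
#' @param max_cost Strict upper bound on cumulative cost for a link.
#' @return An undirected igraph whose vertices carry `x`, `y` (metres) and
#'   grid `row`, `col` attributes.
#' @export
least_cost_links <- function(raster, patches, max_cost) {
  if (max_cost < 0) {
    abort("`max_cost` must be non-negative.", class = "clustlink_configuration_error")
  }
  nr <- nrow(raster$cost)
  vids <- (patches$col - 1L) * nr + patches$row
  D <- patch_cost_matrix(raster, patches)
  linked <- which(D < max_cost & upper.tri(D), arr.ind = TRUE)
  g <- igraph::make_empty_graph(nrow(patches), directed = FALSE)
  if (nrow(linked)) {
    g <- igraph::add_edges(g, t(linked))
  }
  igraph::V(g)$name <- patches$label
  igraph::V(g)$x <- patches$x
  igraph::V(g)$y <- patches$y
  igraph::V(g)$row <- patches$row
  igraph::V(g)$col <- patches$col
  g
}

#' Pairwise least-cost distances between patches
#'
#' @inheritParams least_cost_links
#' @return A symmetric matrix of minimal cumulative traversal costs.
#' @export
patch_cost_matrix <- function(raster, patches) {
  nr <- nrow(raster$cost)
  vids <- (patches$col - 1L) * nr + patches$row
  g <- grid_graph(raster$cost)
  igraph::distances(g, v = vids, to = vids, weights = igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Generate a synthetic landscape-based habitat network
#'
#' Composes [synthesize_cost_raster()], [allocate_patches()] and
#' [least_cost_links()] and retries with fresh sub-seeds (at most
#' `max_attempts`) until the patch count falls in `patch_range` — the size
#' window of the stream-network tiles the generator emulates.
#'
#' @param config A [landscape_config()].
#' @param seed Integer master seed.
#' @param patch_range Acceptable inclusive patch-count window.
#' @param max_attempts Retry budget.
#' @return An igraph habitat network with metric vertex coordinates and
#'   graph attributes `allocation`, `max_cost`, `seed`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L,
                               patch_range = c(54, 111), max_attempts = 20) {
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 max_attempts * 2))
  for (a in seq_len(max_attempts)) {
    raster <- synthesize_cost_raster(config, seed = sub_seeds[2 * a - 1])
    patches <- allocate_patches(raster, config, seed = sub_seeds[2 * a])
    if (nrow(patches) < patch_range[1] || nrow(patches) > patch_range[2]) next
    g <- least_cost_links(raster, patches, config$max_cost)
    g$allocation <- config$allocation
    g$max_cost <- config$max_cost
    g$seed <- as.integer(seed)
    return(g)
  }
  abort(sprintf(
    "no landscape with %d-%d patches after %d attempts; widen `stream_cells`.",
    patch_range[1], patch_range[2], max_attempts),
    class = "clustlink_generation_error")
}
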