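# Independent oracles and fixture builders shared across the suite.

# Watts-Strogatz average clustering via igraph, independent of the package's
# own bookkeeping (isolated / degree-1 nodes count as 0).
oracle_clustering <- function(g) {
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

# random named simple graph with density p
random_named_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}

# add one link to an igraph by labels
plus_link <- function(g, u, v) igraph::add_edges(g, c(u, v))

# brute-force per-node triangle counts by enumerating all node triples
triples_triangle_count <- function(g) {
  labs <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  tri <- setNames(numeric(length(labs)), labs)
  n <- length(labs)
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (A[i, j] && A[j, k] && A[i, k]) tri[c(i, j, k)] <- tri[c(i, j, k)] + 1
  }
  tri
}

# plain-R Dijkstra over an 8-connected cost grid, with the same edge-weight
# convention as the package (mean of cell costs, sqrt(2) x for diagonals)
# but an independent O(V^2) implementation.
ref_grid_dijkstra <- function(cost, from_rc) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- nr * nc
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  id <- function(r, c) (c - 1) * nr + r
  dist[id(from_rc[1], from_rc[2])] <- 0
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1
    uc <- ((u - 1) %/% nr) + 1
    for (s in seq_len(nrow(steps))) {
      r2 <- ur + steps$dr[s]; c2 <- uc + steps$dc[s]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- (cost[ur, uc] + cost[r2, c2]) / 2
      if (steps$dr[s] != 0 && steps$dc[s] != 0) w <- w * sqrt(2)
      v <- id(r2, c2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# is a logical mask 8-connected?
mask_connected <- function(mask) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) return(FALSE)
  idx <- seq_len(nrow(cells))
  key <- paste(cells[, 1], cells[, 2])
  lookup <- setNames(idx, key)
  edges <- integer(0)
  for (i in idx) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- lookup[paste(cells[i, 1] + dr, cells[i, 2] + dc)]
      if (!is.na(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(nrow(cells), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no == 1
}

# tiny uniform-cost raster for least-cost tests
uniform_raster <- function(n, cost_value = 50, cell_size = 25) {
  structure(list(cost = matrix(cost_value, n, n),
                 stream = matrix(TRUE, n, n),
                 cell_size = cell_size),
            class = "cost_raster")
}

patch_tbl <- function(rows, cols, cell_size = 25) {
  tibble::tibble(label = sprintf("p%03d", seq_along(rows)),
                 row = rows, col = cols,
                 x = (cols - 0.5) * cell_size, y = (rows - 0.5) * cell_size)
}
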