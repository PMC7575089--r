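#' Read a network from file
#'
#' Edge lists are two-column CSV files (optional `source,target` header,
#' labels read as strings); GraphML files are read through igraph. Both are
#' validated: self-loops and duplicate links are rejected with the
#' offending pair named. A coordinates CSV (`label,x_m,y_m`) may be
#' attached as metric vertex coordinates.
#'
#' @param path Path to the graph file.
#' @param format `"auto"` (by file extension), `"edgelist"` or `"graphml"`.
#' @param coords_path Optional coordinates CSV.
#' @return An undirected simple igraph with named vertices.
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "graphml"),
                            coords_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  g <- if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    read_edgelist_csv(path)
  }
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
  validate_links(g)
  g <- ensure_names(g)
  if (!is.null(coords_path)) {
    co <- readr::read_csv(coords_path, col_types = readr::cols(
      label = readr::col_character(), x_m = readr::col_double(),
      y_m = readr::col_double()))
    missing <- setdiff(igraph::V(g)$name, co$label)
    if (length(missing)) {
      abort(paste0("coordinates missing for node(s): ",
                   paste(missing, collapse = ", ")),
            class = "clustlink_format_error")
    }
    idx <- match(igraph::V(g)$name, co$label)
    igraph::V(g)$x <- co$x_m[idx]
    igraph::V(g)$y <- co$y_m[idx]
  }
  g
}

read_edgelist_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0(path, ": empty edge list."), class = "clustlink_format_error")
  }
  if (grepl("^\\s*source\\s*,\\s*target\\s*$", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, ",")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("%s: line %d is not a `u,v` pair: '%s'.",
                  path, bad[1], lines[bad[1]]),
          class = "clustlink_format_error")
  }
  el <- trimws(do.call(rbind, parts))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

validate_links <- function(g) {
  if (igraph::any_loop(g)) {
    e <- igraph::ends(g, igraph::E(g)[igraph::which_loop(g)][1])
    abort(paste0("self-loop at node '", e[1], "' is not allowed."),
          class = "clustlink_format_error")
  }
  if (igraph::any_multiple(g)) {
    e <- igraph::ends(g, igraph::E(g)[igraph::which_multiple(g)][1])
    abort(paste0("duplicate link (", e[1], ", ", e[2], ") is not allowed."),
          class = "clustlink_format_error")
  }
  invisible(g)
}

#' Write a network to file
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param format `"auto"`, `"edgelist"` (CSV with `source,target` header) or
#'   `"graphml"`.
#' @param coords_path Optional path for a `label,x_m,y_m` coordinates CSV
#'   (written when the graph has `x`/`y` vertex attributes).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("auto", "edgelist", "graphml"),
                             coords_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  graph <- ensure_names(graph)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    readr::write_csv(tibble(source = el[, 1], target = el[, 2]), path)
  }
  if (!is.null(coords_path)) {
    xs <- igraph::V(graph)$x
    ys <- igraph::V(graph)$y
    if (is.null(xs) || is.null(ys)) {
      abort("graph has no `x`/`y` coordinates to write.",
            class = "clustlink_configuration_error")
    }
    readr::write_csv(tibble(label = igraph::V(graph)$name, x_m = xs, y_m = ys),
                     coords_path)
  }
  invisible(path)
}

#' Write a results table as CSV
#'
#' Deterministic byte output: stable column order as given, no row
#' reordering.
#'
#' @param table A nonempty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("`table` must be a nonempty data frame.", class = "clustlink_domain_error")
  }
  readr::write_csv(table, path)
  invisible(path)
}
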