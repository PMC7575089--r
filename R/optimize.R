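new_link_plan <- function(links, initial_C, strategy, n_candidates,
                          seed = NA_integer_, ties = NULL) {
  structure(
    list(links = links, initial_C = initial_C,
         final_C = if (nrow(links)) links$clustering_after[nrow(links)] else initial_C,
         strategy = strategy, m = nrow(links), n_candidates = n_candidates,
         seed = seed, ties = ties),
    class = "link_plan"
  )
}

#' @export
print.link_plan <- function(x, ...) {
  cat("<link_plan> strategy = ", x$strategy, ", m = ", x$m,
      ", C_G: ", format(x$initial_C, digits = 6), " -> ",
      format(x$final_C, digits = 6), "\n", sep = "")
  print(x$links)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.link_plan <- function(x, ...) x$links

#' @exportS3Method generics::glance
glance.link_plan <- function(x, ...) {
  tibble(strategy = x$strategy, m = x$m, initial_C = x$initial_C,
         final_C = x$final_C, delta_C = x$final_C - x$initial_C,
         n_candidates = x$n_candidates, seed = x$seed)
}

# Scores for the candidate rows of a state, via the vectorized all-pairs pass.
candidate_scores <- function(state, candidates) {
  scores <- score_all_pairs(state)
  scores[cbind(candidates$u, candidates$v)]
}

#' Best single link to add
#'
#' Evaluates every candidate pair with the incremental clustering update and
#' returns one that maximises the clustering coefficient of the extended
#' network. Ties are broken by candidate order (lexicographic by label
#' pair), and all tied maximisers are reported.
#'
#' @param x A graph or [clustering_state()].
#' @param candidates A [all_missing_links()]-style candidate set; defaults to
#'   all missing pairs.
#' @param tol Absolute tolerance within which scores count as tied.
#' @return A list with `u`, `v` (the first maximiser in candidate order),
#'   `clustering_after` (the maximum), and `maximizers`, a tibble of all
#'   tied pairs.
#' @examples
#' best_single_link(example_graph())$clustering_after # 0.5
#' @export
best_single_link <- function(x, candidates = NULL, tol = 1e-12) {
  state <- as_clustering_state(x)
  if (is.null(candidates)) candidates <- all_missing_links(state$graph)
  check_candidates(state, candidates)
  if (nrow(candidates) == 0) {
    abort("the candidate set is empty.", class = "clustlink_domain_error")
  }
  sc <- candidate_scores(state, candidates)
  best <- max(sc)
  tied <- which(sc >= best - tol)
  list(u = candidates$u[tied[1]], v = candidates$v[tied[1]],
       clustering_after = best,
       maximizers = tibble(u = candidates$u[tied], v = candidates$v[tied],
                           clustering_after = sc[tied]))
}

check_m <- function(candidates, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    abort("`m` must be a single positive integer.", class = "clustlink_domain_error")
  }
  if (nrow(candidates) < m) {
    abort(sprintf("need %d candidate links but only %d are available.",
                  m, nrow(candidates)),
          class = "clustlink_domain_error")
  }
  invisible(m)
}

#' Greedy link addition
#'
#' Adds `m` links one at a time, each round committing a link that maximises
#' the clustering coefficient of the *current* network (the chosen link is
#' removed from the candidate pool, and all remaining candidates are
#' re-scored, since an inserted link changes the common-neighbour counts of
#' other pairs).
#'
#' @inheritParams best_single_link
#' @param m Number of links to add.
#' @return A `link_plan`: chosen links in insertion order with the clustering
#'   trajectory; see [tidy()] and [glance()] methods.
#' @export
add_links_greedy <- function(x, candidates = NULL, m = 1, tol = 1e-12) {
  state <- as_clustering_state(x)
  if (is.null(candidates)) candidates <- all_missing_links(state$graph)
  check_candidates(state, candidates)
  check_m(candidates, m)
  initial <- state$C
  rows <- vector("list", m)
  ties <- integer(m)
  for (i in seq_len(m)) {
    pick <- best_single_link(state, candidates, tol = tol)
    state <- apply_link(state, pick$u, pick$v)
    ties[i] <- nrow(pick$maximizers)
    rows[[i]] <- tibble(rank = i, u = pick$u, v = pick$v,
                        clustering_after = state$C)
    candidates <- candidates[!(candidates$u == pick$u & candidates$v == pick$v), ]
  }
  new_link_plan(dplyr::bind_rows(rows), initial, "greedy",
                n_candidates = nrow(candidates) + m, ties = ties)
}

#' Lazy Greedy link addition
#'
#' Scores every candidate once against the original network, sorts the
#' scores in decreasing order (stable: ties keep candidate order) and takes
#' the top `m` links in one pass — cheaper than [add_links_greedy()] but
#' blind to the interaction between the inserted links.
#'
#' @inheritParams add_links_greedy
#' @return A `link_plan`; the trajectory is computed by committing the `m`
#'   links in sorted order.
#' @export
add_links_lazy_greedy <- function(x, candidates = NULL, m = 1, tol = 1e-12) {
  state <- as_clustering_state(x)
  if (is.null(candidates)) candidates <- all_missing_links(state$graph)
  check_candidates(state, candidates)
  check_m(candidates, m)
  initial <- state$C
  sc <- candidate_scores(state, candidates)
  # select the top m with the same tie rule as best_single_link: scores
  # within `tol` count as equal and the earliest candidate wins (a plain
  # stable sort would instead order mathematically-tied scores by their
  # floating-point noise)
  top <- integer(m)
  remaining <- seq_along(sc)
  for (i in seq_len(m)) {
    mx <- max(sc[remaining])
    pick <- remaining[sc[remaining] >= mx - tol][1]
    top[i] <- pick
    remaining <- remaining[remaining != pick]
  }
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    state <- apply_link(state, candidates$u[top[i]], candidates$v[top[i]])
    rows[[i]] <- tibble(rank = i, u = candidates$u[top[i]],
                        v = candidates$v[top[i]], clustering_after = state$C)
  }
  new_link_plan(dplyr::bind_rows(rows), initial, "lazy_greedy",
                n_candidates = nrow(candidates))
}

#' Exhaustively optimal link addition
#'
#' Enumerates subsets of `m` candidate links and returns one whose joint
#' insertion maximises the clustering coefficient — the (exponential-cost)
#' optimum the heuristics are measured against. Ties resolve to the
#' lexicographically smallest subset in candidate order. `m = 2`, the case
#' used throughout the ensemble experiments, is computed by a vectorized
#' pass: fix the first link, re-score all remaining candidates at once.
#'
#' @inheritParams add_links_greedy
#' @param budget Maximum number of subsets to enumerate before refusing;
#'   guards against accidental combinatorial blow-up.
#' @return A `link_plan` with strategy `"exhaustive"`.
#' @examples
#' tidy(add_links_exhaustive(example_graph(), m = 2))
#' @export
add_links_exhaustive <- function(x, candidates = NULL, m = 1,
                                 budget = 2e6, tol = 1e-12) {
  state <- as_clustering_state(x)
  if (is.null(candidates)) candidates <- all_missing_links(state$graph)
  check_candidates(state, candidates)
  check_m(candidates, m)
  nc <- nrow(candidates)
  # m <= 2 runs as a vectorized sweep with nc outer passes, so the subset
  # count only measures the work of the generic enumeration path
  work <- if (m <= 2) nc else choose(nc, m)
  if (work > budget) {
    abort(sprintf(
      "enumeration of C(%d, %d) subsets exceeds the budget of %g; restrict the candidate set or reduce m.",
      nc, m, budget), class = "clustlink_resource_error")
  }
  initial <- state$C
  if (m == 1) {
    pick <- best_single_link(state, candidates, tol = tol)
    best_idx <- which(candidates$u == pick$u & candidates$v == pick$v)[1]
  } else if (m == 2) {
    # vectorized sweep on the core view: fix the first link, score every
    # remaining candidate at once via the all-pairs pass
    ui <- match(candidates$u, state$labels)
    vi <- match(candidates$v, state$labels)
    lin <- (vi - 1L) * state$n + ui      # column-major linear indices
    best <- -Inf
    best_pair <- NULL
    for (i in seq_len(nc - 1)) {
      cs1 <- core_apply(state, ui[i], vi[i])
      sc <- score_core(cs1)[lin[(i + 1):nc]]
      j <- which.max(sc)
      if (length(j) && sc[j] > best + tol) {
        best <- sc[j]
        best_pair <- c(i, i + j)
      }
    }
    best_idx <- best_pair
  } else {
    best <- -Inf
    best_idx <- NULL
    ui <- match(candidates$u, state$labels)
    vi <- match(candidates$v, state$labels)
    subsets <- combn(nc, m)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      cs <- state
      for (i in idx) cs <- core_apply(cs, ui[i], vi[i])
      if (cs$C > best + tol) {
        best <- cs$C
        best_idx <- idx
      }
    }
  }
  rows <- vector("list", length(best_idx))
  st <- state
  for (i in seq_along(best_idx)) {
    st <- apply_link(st, candidates$u[best_idx[i]], candidates$v[best_idx[i]])
    rows[[i]] <- tibble(rank = i, u = candidates$u[best_idx[i]],
                        v = candidates$v[best_idx[i]], clustering_after = st$C)
  }
  new_link_plan(dplyr::bind_rows(rows), initial, "exhaustive",
                n_candidates = nc)
}

#' Uniform random link addition
#'
#' The baseline strategy: `m` distinct candidate links sampled uniformly
#' without replacement, reproducible from `seed`.
#'
#' @inheritParams add_links_greedy
#' @param seed Integer seed controlling the draw.
#' @return A `link_plan` with strategy `"random"` and the seed recorded.
#' @export
add_links_random <- function(x, candidates = NULL, m = 1, seed = 1L) {
  state <- as_clustering_state(x)
  if (is.null(candidates)) candidates <- all_missing_links(state$graph)
  check_candidates(state, candidates)
  check_m(candidates, m)
  idx <- withr::with_seed(seed, sample.int(nrow(candidates), m))
  rows <- vector("list", m)
  initial <- state$C
  for (i in seq_along(idx)) {
    state <- apply_link(state, candidates$u[idx[i]], candidates$v[idx[i]])
    rows[[i]] <- tibble(rank = i, u = candidates$u[idx[i]],
                        v = candidates$v[idx[i]], clustering_after = state$C)
  }
  new_link_plan(dplyr::bind_rows(rows), initial, "random",
                n_candidates = nrow(candidates), seed = as.integer(seed))
}

#' Dispatch a link-addition strategy by name
#'
#' @inheritParams add_links_greedy
#' @param strategy One of `"greedy"`, `"lazy_greedy"`, `"exhaustive"`,
#'   `"random"`.
#' @param seed Seed, used by the random strategy only.
#' @return A `link_plan`.
#' @export
add_links <- function(x, strategy, candidates = NULL, m = 1, seed = 1L) {
  switch(match.arg(strategy, c("greedy", "lazy_greedy", "exhaustive", "random")),
    greedy = add_links_greedy(x, candidates, m),
    lazy_greedy = add_links_lazy_greedy(x, candidates, m),
    exhaustive = add_links_exhaustive(x, candidates, m),
    random = add_links_random(x, candidates, m, seed = seed)
  )
}

#' Apply a link plan to a graph
#'
#' @param graph The graph the plan was computed for.
#' @param plan A `link_plan`.
#' @return The igraph object with the plan's links inserted.
#' @export
apply_plan <- function(graph, plan) {
  graph <- ensure_names(graph)
  igraph::add_edges(graph, rbind(plan$links$u, plan$links$v))
}
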