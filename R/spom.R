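#' Parameters of the patch-occupancy metapopulation model
#'
#' A discrete-time stochastic patch-occupancy model (SPOM) with
#' neighbourhood-rescued extinction and independent-per-neighbour
#' colonization. Each synchronous step has two phases. First, every
#' occupied patch goes extinct with probability
#' `max(0, e - rescue * (occupied neighbours))`, clamped to `[0, 1]`: a
#' well-connected occupied neighbourhood rescues a patch from local
#' extinction. Second, every patch empty after the extinction phase is
#' recolonised with probability `1 - (1 - c)^(occupied neighbours)`:
#' each occupied neighbour is an independent colonisation source.
#'
#' Stationarity is operationalised as a fixed burn-in followed by a fixed
#' averaging window (deterministic given the seed), rather than a
#' convergence test.
#'
#' @param e Per-step local extinction risk of an occupied patch, in `[0, 1]`.
#' @param rescue Reduction of `e` per occupied neighbour (>= 0).
#' @param c Per-occupied-neighbour colonisation probability, in `[0, 1]`.
#' @param burn_in Steps discarded before averaging.
#' @param window Steps averaged to estimate stationary occupancy.
#' @param replicates Independent simulation replicates averaged over.
#' @return A list of class `spom_params`.
#' @export
spom_params <- function(e = 0.2, rescue = 0.02, c = 0.3,
                        burn_in = 200, window = 100, replicates = 50) {
  if (e < 0 || e > 1 || c < 0 || c > 1 || rescue < 0) {
    abort("`e` and `c` must lie in [0, 1] and `rescue` must be >= 0.",
          class = "clustlink_configuration_error")
  }
  if (burn_in < 1 || window < 1 || replicates < 1) {
    abort("`burn_in`, `window` and `replicates` must be >= 1.",
          class = "clustlink_configuration_error")
  }
  structure(list(e = e, rescue = rescue, c = c, burn_in = as.integer(burn_in),
                 window = as.integer(window), replicates = as.integer(replicates)),
            class = "spom_params")
}

#' Random habitat loss
#'
#' Permanently removes a uniformly chosen `round(fraction * n)` of the
#' patches together with all their links.
#'
#' @param graph An igraph habitat network.
#' @param fraction Fraction of patches lost, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The reduced igraph.
#' @export
remove_random_patches <- function(graph, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1].", class = "clustlink_domain_error")
  }
  graph <- ensure_names(graph)
  n <- igraph::vcount(graph)
  drop <- withr::with_seed(seed, sample.int(n, round(fraction * n)))
  igraph::delete_vertices(graph, drop)
}

# one synchronous extinction-then-colonization step for an occupancy matrix
# (nodes x replicates); alive masks removed patches out of the dynamics
spom_step <- function(occ, A, params) {
  nb <- A %*% occ
  ext_p <- pmin(1, pmax(0, params$e - params$rescue * nb))
  occ <- occ * (matrix(runif(length(occ)), nrow(occ)) >= ext_p)
  nb <- A %*% occ
  col_p <- 1 - (1 - params$c)^nb
  occ + (occ == 0) * (matrix(runif(length(occ)), nrow(occ)) < col_p)
}

#' Stationary occupancy of a metapopulation
#'
#' Runs the SPOM from an all-occupied start and returns the fraction of
#' occupied patches, averaged over the post-burn-in window and over
#' replicates. An empty graph has occupancy 0. All replicates run
#' vectorised with one uniform draw per patch, phase and step, so results
#' are bit-for-bit reproducible from the seed — and comparable across
#' graphs sharing the same node set (common random numbers).
#'
#' @param graph An igraph habitat network (possibly after habitat loss).
#' @param params A [spom_params()].
#' @param seed Integer seed.
#' @return Mean occupied fraction in `[0, 1]`.
#' @export
stationary_occupancy <- function(graph, params = spom_params(), seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0) return(0)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  storage.mode(A) <- "double"
  withr::with_seed(seed, {
    occ <- matrix(1, n, params$replicates)
    acc <- 0
    for (s in seq_len(params$burn_in + params$window)) {
      occ <- spom_step(occ, A, params)
      if (s > params$burn_in) acc <- acc + mean(occ)
    }
    acc / params$window
  })
}

#' Robustness curve under random habitat loss
#'
#' For each habitat-loss fraction, repeatedly removes that fraction of
#' patches at random and measures the stationary occupancy of the surviving
#' metapopulation; occupancy is reported relative to the surviving patches
#' (set `relative_to = "original"` to divide by the pre-loss patch count
#' instead). The area under the resulting occupancy-vs-loss curve (AUC,
#' trapezoidal over `[0, 1]`) is the scalar robustness measure.
#'
#' Replicates are coupled across calls sharing a seed and node set: the
#' removal draws and the per-patch dynamics draws are identical, so curves
#' for a baseline network and the same network with added links are
#' directly comparable.
#'
#' @inheritParams stationary_occupancy
#' @param loss_grid Strictly increasing habitat-loss fractions in `[0, 1]`.
#' @param relative_to Occupancy denominator: surviving or original patches.
#' @return An object of class `robustness_curve`: a tibble with columns
#'   `loss`, `occupancy`, `se`, plus attributes `auc` and `params`.
#' @export
robustness_curve <- function(graph, params = spom_params(),
                             loss_grid = seq(0, 0.9, by = 0.1), seed = 1L,
                             relative_to = c("surviving", "original")) {
  relative_to <- match.arg(relative_to)
  if (any(diff(loss_grid) <= 0) || any(loss_grid < 0 | loss_grid > 1)) {
    abort("`loss_grid` must be strictly increasing within [0, 1].",
          class = "clustlink_domain_error")
  }
  graph <- ensure_names(graph)
  n <- igraph::vcount(graph)
  reps <- params$replicates
  rep_seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 2 * reps * length(loss_grid)),
    nrow = 2 * reps))
  one_rep_params <- params
  one_rep_params$replicates <- 1L
  rows <- purrr::imap(loss_grid, function(f, li) {
    occ <- vapply(seq_len(reps), function(r) {
      g_surv <- remove_random_patches(graph, f, seed = rep_seeds[2 * r - 1, li])
      occ_frac <- stationary_occupancy(g_surv, one_rep_params,
                                       seed = rep_seeds[2 * r, li])
      if (relative_to == "original") occ_frac * igraph::vcount(g_surv) / n
      else occ_frac
    }, numeric(1))
    tibble(loss = f, occupancy = mean(occ),
           se = stats::sd(occ) / sqrt(reps))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("robustness_curve", class(out))
  attr(out, "params") <- params
  attr(out, "auc") <- auc(out)
  out
}

#' Area under a robustness curve
#'
#' Trapezoidal integral of occupancy over habitat loss in `[0, 1]`. A curve
#' whose grid does not reach 0 or 1 is extended flat with its boundary
#' values, never extrapolated.
#'
#' @param curve A [robustness_curve()] (or any data frame with `loss` and
#'   `occupancy` columns).
#' @return The AUC, in `[0, 1]`.
#' @export
auc <- function(curve) {
  x <- curve$loss
  y <- curve$occupancy
  if (length(x) < 2) {
    abort("need at least two curve points.", class = "clustlink_domain_error")
  }
  if (x[1] > 0) { x <- c(0, x); y <- c(y[1], y) }
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Compare link-addition strategies by robustness gain
#'
#' For each strategy and each number of added links `m`, optimises the
#' links over the distance-restricted candidate set, reruns the robustness
#' simulation with the same seed (common random numbers against the
#' baseline) and reports the change in AUC.
#'
#' @param graph An igraph habitat network with metric coordinates.
#' @param params A [spom_params()].
#' @param m_values Numbers of links to add.
#' @param strategies Subset of `"greedy"`, `"lazy_greedy"`, `"random"`.
#' @param max_dist Euclidean candidate restriction in metres.
#' @param loss_grid Habitat-loss grid for the curves.
#' @param seed Integer seed (drives removal, dynamics and the random
#'   strategy).
#' @return A tibble: `strategy`, `m`, `auc_baseline`, `auc_after`,
#'   `delta_auc`, `delta_C`, `n`, `n_candidates`, `seed`. Rows with fewer
#'   candidates than `m` are skipped with a warning.
#' @export
compare_strategies <- function(graph, params = spom_params(),
                               m_values = seq(5, 30, by = 5),
                               strategies = c("greedy", "lazy_greedy", "random"),
                               max_dist = 2500,
                               loss_grid = seq(0, 0.9, by = 0.1), seed = 1L) {
  graph <- ensure_names(graph)
  strategies <- match.arg(strategies, several.ok = TRUE)
  cand <- distance_restricted_links(graph, max_dist)
  baseline <- auc(robustness_curve(graph, params, loss_grid, seed = seed))
  n <- igraph::vcount(graph)
  grid <- tidyr_expand(strategies, m_values)
  rows <- purrr::pmap(grid, function(strategy, m) {
    if (nrow(cand) < m) {
      warn(sprintf("skipping %s m=%d: only %d candidates within %g m.",
                   strategy, m, nrow(cand), max_dist))
      return(NULL)
    }
    plan <- add_links(graph, strategy, cand, m = m, seed = seed)
    g2 <- apply_plan(graph, plan)
    after <- auc(robustness_curve(g2, params, loss_grid, seed = seed))
    tibble(strategy = strategy, m = m, auc_baseline = baseline,
           auc_after = after, delta_auc = after - baseline,
           delta_C = plan$final_C - plan$initial_C,
           n = n, n_candidates = nrow(cand), seed = as.integer(seed))
  })
  dplyr::bind_rows(rows)
}

tidyr_expand <- function(strategies, m_values) {
  tibble(strategy = rep(strategies, each = length(m_values)),
         m = rep(m_values, times = length(strategies)))
}
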