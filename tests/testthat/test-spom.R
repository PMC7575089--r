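fast_params <- function(...) {
  args <- list(...)
  defaults <- list(e = 0.2, rescue = 0.02, c = 0.3,
                   burn_in = 30, window = 15, replicates = 5)
  do.call(spom_params, utils::modifyList(defaults, args))
}

test_that("parameter validation rejects impossible probabilities", {
  expect_error(spom_params(e = 1.2), class = "clustlink_configuration_error")
  expect_error(spom_params(c = -0.1), class = "clustlink_configuration_error")
  expect_error(spom_params(burn_in = 0), class = "clustlink_configuration_error")
})

test_that("random habitat loss behaves at the boundaries and is uniform", {
  g <- example_graph()
  expect_identical(igraph::as_edgelist(remove_random_patches(g, 0, seed = 1)),
                   igraph::as_edgelist(g))
  expect_equal(igraph::vcount(remove_random_patches(g, 1, seed = 1)), 0)
  kept <- table(unlist(lapply(1:2000, function(s) {
    igraph::V(remove_random_patches(g, 0.5, seed = s))$name
  })))
  expect_gt(suppressWarnings(chisq.test(kept))$p.value, 1e-3)
})

test_that("without extinction occupancy is exactly 1; without colonisation it dies", {
  g <- generate_standard("random", "sparse", n = 40, seed = 2)
  expect_equal(stationary_occupancy(g, fast_params(e = 0), seed = 1), 1)
  dead <- stationary_occupancy(g, fast_params(e = 0.5, c = 0, burn_in = 300,
                                              window = 20), seed = 1)
  expect_equal(dead, 0)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(stationary_occupancy(empty, fast_params(), seed = 1), 0)
})

test_that("a single isolated patch follows the two-state chain closed form", {
  g <- igraph::make_empty_graph(1, directed = FALSE)
  e <- 0.05
  params <- spom_params(e = e, c = 0.9, burn_in = 10, window = 20,
                        replicates = 4000)
  sim <- stationary_occupancy(g, params, seed = 42)
  # no neighbours: survives each step w.p. 1 - e, never recolonised, so
  # occupancy at step t is (1-e)^t; average over the window analytically
  steps <- (params$burn_in + 1):(params$burn_in + params$window)
  expected <- mean((1 - e)^steps)
  expect_lt(abs(sim - expected), 4 * sqrt(0.25 / params$replicates) + 0.005)
})

test_that("robustness curves are deterministic, bounded and anchored", {
  g <- generate_standard("random", "sparse", n = 40, seed = 5)
  c1 <- robustness_curve(g, fast_params(), loss_grid = c(0, 0.5, 1), seed = 9)
  c2 <- robustness_curve(g, fast_params(), loss_grid = c(0, 0.5, 1), seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "auc"), attr(c2, "auc"))
  expect_true(all(c1$occupancy >= 0 & c1$occupancy <= 1))
  expect_equal(c1$occupancy[c1$loss == 1], 0)
  perfect <- robustness_curve(g, fast_params(e = 0), loss_grid = c(0, 0.5, 0.9),
                              seed = 1)
  expect_true(all(perfect$occupancy == 1))
  expect_equal(attr(perfect, "auc"), 1)
  expect_error(robustness_curve(g, fast_params(), loss_grid = c(0.5, 0.2)),
               class = "clustlink_domain_error")
})

test_that("mean occupancy does not increase with habitat loss (within noise)", {
  g <- generate_standard("random", "sparse", n = 50, seed = 31)
  cur <- robustness_curve(g, fast_params(replicates = 100, burn_in = 40,
                                         window = 20),
                          loss_grid = seq(0, 1, 0.25), seed = 3)
  jump <- diff(cur$occupancy)
  tol <- 2 * sqrt(head(cur$se, -1)^2 + cur$se[-1]^2)
  expect_true(all(jump <= tol + 1e-12))
})

test_that("trapezoidal AUC handles toy curves and boundary extension", {
  toy <- tibble::tibble(loss = c(0, 0.5, 1), occupancy = c(1, 0.5, 0))
  expect_equal(auc(toy), 0.5)
  expect_equal(auc(tibble::tibble(loss = c(0, 1), occupancy = c(1, 1))), 1)
  expect_equal(auc(tibble::tibble(loss = c(0, 1), occupancy = c(0, 0))), 0)
  # flat extension to the boundaries, no extrapolation
  expect_equal(auc(tibble::tibble(loss = c(0.25, 0.75), occupancy = c(1, 0))),
               0.25 + 0.25)
  expect_error(auc(tibble::tibble(loss = 0.5, occupancy = 1)),
               class = "clustlink_domain_error")
})

test_that("adding links never hurts occupancy under common random numbers", {
  g <- generate_standard("random", "sparse", n = 45, seed = 12)
  plan <- add_links_greedy(g, m = 8)
  g_plus <- apply_plan(g, plan)
  params <- fast_params(replicates = 8, burn_in = 40, window = 20)
  grid <- seq(0, 0.8, 0.2)
  base <- robustness_curve(g, params, grid, seed = 101)
  more <- robustness_curve(g_plus, params, grid, seed = 101)
  expect_true(all(more$occupancy >= base$occupancy - 1e-12))
  expect_gte(attr(more, "auc"), attr(base, "auc") - 1e-12)
})

test_that("strategy comparison reports coherent AUC deltas", {
  g <- generate_landscape(landscape_config("clustered"), seed = 3)
  params <- fast_params(replicates = 4, burn_in = 30, window = 15)
  out <- compare_strategies(g, params, m_values = c(2, 6),
                            strategies = c("greedy", "random"),
                            loss_grid = seq(0, 1, 0.25), seed = 8)
  expect_equal(nrow(out), 4)
  expect_equal(out$delta_auc, out$auc_after - out$auc_baseline, tolerance = 1e-12)
  expect_equal(length(unique(out$auc_baseline)), 1)
  # greedy strictly raises clustering; the random baseline rarely does
  expect_true(all(out$delta_C[out$strategy == "greedy"] > 0))
  expect_s3_class(plot_strategy_comparison(out), "ggplot")
})
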