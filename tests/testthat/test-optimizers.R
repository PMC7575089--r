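test_that("the single best link and its ties are found on the worked example", {
  g <- example_graph()
  pick <- best_single_link(g)
  expect_equal(pick$clustering_after, 0.5)
  expect_setequal(paste(pick$maximizers$u, pick$maximizers$v), c("d e", "u v"))
  # first maximiser in candidate order is returned
  expect_equal(c(pick$u, pick$v), c("d", "e"))
  expect_error(best_single_link(igraph::make_full_graph(4)),
               class = "clustlink_domain_error")
})

test_that("best single link equals the brute-force maximum over candidates", {
  for (seed in 1:20) {
    g <- random_named_graph(12 + (seed %% 5) * 6, 0.15, seed + 40)
    cand <- all_missing_links(g)
    if (nrow(cand) == 0) next
    brute <- vapply(seq_len(nrow(cand)), function(i) {
      oracle_clustering(plus_link(g, cand$u[i], cand$v[i]))
    }, numeric(1))
    expect_equal(best_single_link(g, cand)$clustering_after, max(brute),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive two-link optimum matches the worked example", {
  ex <- add_links_exhaustive(example_graph(), m = 2)
  expect_equal(ex$final_C, 0.625)
  expect_setequal(paste(ex$links$u, ex$links$v), c("b e", "d e"))
})

test_that("all strategies coincide at m = 1 and respect the tie-break order", {
  for (seed in c(3, 17, 42)) {
    g <- random_named_graph(20, 0.12, seed)
    pick <- best_single_link(g)
    for (p in list(add_links_greedy(g, m = 1), add_links_lazy_greedy(g, m = 1),
                   add_links_exhaustive(g, m = 1))) {
      expect_equal(p$links$u, pick$u)
      expect_equal(p$links$v, pick$v)
      expect_equal(p$final_C, pick$clustering_after, tolerance = 1e-13)
    }
  }
})

test_that("reported clustering never drifts from a rebuilt graph", {
  for (seed in c(5, 23)) {
    g <- random_named_graph(18, 0.15, seed + 60)
    for (plan in list(add_links_greedy(g, m = 3),
                      add_links_lazy_greedy(g, m = 3),
                      add_links_exhaustive(g, m = 2),
                      add_links_random(g, m = 3, seed = seed))) {
      rebuilt <- g
      for (i in seq_len(nrow(plan$links))) {
        rebuilt <- plus_link(rebuilt, plan$links$u[i], plan$links$v[i])
      }
      expect_equal(plan$final_C, graph_clustering(rebuilt), tolerance = 1e-12)
      expect_equal(plan$final_C, oracle_clustering(rebuilt), tolerance = 1e-12)
      expect_equal(plan$links$clustering_after[nrow(plan$links)], plan$final_C)
    }
  }
})

test_that("the exhaustive optimum dominates both heuristics", {
  for (seed in 1:15) {
    g <- random_named_graph(10 + (seed %% 4) * 5, 0.2, seed + 90)
    if (nrow(all_missing_links(g)) < 2) next
    opt <- add_links_exhaustive(g, m = 2)$final_C
    expect_gte(opt + 1e-12, add_links_greedy(g, m = 2)$final_C)
    expect_gte(opt + 1e-12, add_links_lazy_greedy(g, m = 2)$final_C)
  }
})

test_that("greedy is not always optimal: a two-link witness exists", {
  witness <- NULL
  for (seed in 1:100) {
    n <- 7 + seed %% 6
    g <- random_named_graph(n, 0.25, seed)
    if (nrow(all_missing_links(g)) < 2) next
    gr <- add_links_greedy(g, m = 2)
    ex <- add_links_exhaustive(g, m = 2)
    if (gr$final_C < ex$final_C - 1e-12) {
      witness <- list(greedy = gr$final_C, optimal = ex$final_C)
      break
    }
  }
  expect_false(is.null(witness))
  expect_lt(witness$greedy, witness$optimal)
})

test_that("random insertion is reproducible and uniform over candidates", {
  g <- example_graph()
  cand <- all_missing_links(g)
  expect_identical(tidy(add_links_random(g, cand, m = 3, seed = 77)),
                   tidy(add_links_random(g, cand, m = 3, seed = 77)))
  all_of_them <- add_links_random(g, cand, m = nrow(cand), seed = 1)
  expect_setequal(paste(all_of_them$links$u, all_of_them$links$v),
                  paste(cand$u, cand$v))
  expect_equal(all_of_them$final_C, 1) # complete graph
  st <- clustering_state(g)
  picks <- vapply(seq_len(4000), function(i) {
    p <- add_links_random(st, cand, m = 1, seed = i)
    paste(p$links$u, p$links$v)
  }, character(1))
  tab <- table(factor(picks, levels = paste(cand$u, cand$v)))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-3)
})

test_that("exhaustive enumeration refuses past its subset budget", {
  g <- random_named_graph(30, 0.05, seed = 8)
  expect_error(add_links_exhaustive(g, m = 5, budget = 1000),
               class = "clustlink_resource_error")
})

test_that("plans expose tidy, glance and a trajectory plot", {
  plan <- add_links_greedy(example_graph(), m = 2)
  expect_named(tidy(plan), c("rank", "u", "v", "clustering_after"))
  gl <- glance(plan)
  expect_equal(gl$delta_C, plan$final_C - 7 / 24, tolerance = 1e-13)
  expect_equal(gl$m, 2)
  expect_s3_class(autoplot(plan), "ggplot")
})
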