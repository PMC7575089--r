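test_that("single-endpoint clustering deltas follow the closed form", {
  g <- example_graph()
  # endpoint u of the example insertion: d = 2, T = 0, k = 1
  expect_equal(delta_node_clustering(g, "u", k = 1), 1 / 3)
  # no common neighbour at a node that owns triangles: strictly negative
  expect_lt(delta_node_clustering(g, "w", k = 0), 0)
  # degenerate degrees: recomputation-exact values
  deg1 <- igraph::make_graph(~ a - b, c - d)
  expect_equal(delta_node_clustering(deg1, "a", k = 0), 0)
  iso <- igraph::disjoint_union(igraph::make_full_graph(3),
                                igraph::make_empty_graph(1, directed = FALSE))
  igraph::V(iso)$name <- c("a", "b", "c", "z")
  expect_equal(delta_node_clustering(iso, "z", k = 0), 0)
  expect_error(delta_node_clustering(g, "u", k = -1), class = "clustlink_domain_error")
  expect_error(delta_node_clustering(g, "u", k = 5), class = "clustlink_domain_error")
})

test_that("degree-1 delta equals the recomputed change for k in {0, 1}", {
  # a - b - c plus d: adding (a, c) has k = 1 at both endpoints (d = 1)
  g <- igraph::make_graph(~ a - b - c)
  before <- clustering_state(g)
  expect_equal(delta_node_clustering(before, "a", k = 1), 1)
  after <- clustering_state(plus_link(g, "a", "c"))
  expect_equal(after$local[["a"]] - before$local[["a"]], 1)
  # adding a link with no shared neighbour leaves a degree-1 endpoint at 0
  g2 <- igraph::make_graph(~ a - b, c - d)
  expect_equal(delta_node_clustering(g2, "a", k = 0), 0)
  after2 <- clustering_state(plus_link(g2, "a", "c"))
  expect_equal(after2$local[["a"]], 0)
})

test_that("incremental update equals from-scratch recomputation", {
  g <- example_graph()
  expect_equal(updated_graph_clustering(g, "u", "v"), 1 / 2)
  for (seed in 1:60) {
    n <- 8 + (seed %% 6) * 9
    gg <- random_named_graph(n, 0.04 + 0.07 * (seed %% 10), seed + 1000)
    cand <- all_missing_links(gg)
    if (nrow(cand) == 0) next
    i <- withr::with_seed(seed, sample.int(nrow(cand), 1))
    inc <- updated_graph_clustering(gg, cand$u[i], cand$v[i])
    rebuilt <- graph_clustering(plus_link(gg, cand$u[i], cand$v[i]))
    expect_equal(inc, rebuilt, tolerance = 1e-12)
    expect_equal(inc, oracle_clustering(plus_link(gg, cand$u[i], cand$v[i])),
                 tolerance = 1e-12)
  }
})

test_that("a link between nodes without common neighbours never raises clustering", {
  for (seed in 1:25) {
    gg <- random_named_graph(20, 0.12, seed + 300)
    st <- clustering_state(gg)
    cand <- all_missing_links(gg)
    for (i in seq_len(nrow(cand))) {
      if (length(common_neighbours(st, cand$u[i], cand$v[i])) == 0) {
        expect_lte(updated_graph_clustering(st, cand$u[i], cand$v[i]),
                   st$C + 1e-15)
        break
      }
    }
  }
})

test_that("updating an existing link is a precondition error", {
  g <- example_graph()
  expect_error(updated_graph_clustering(g, "a", "b"),
               class = "clustlink_precondition_error")
  expect_error(apply_link(g, "a", "b"), class = "clustlink_precondition_error")
})

test_that("apply_link commits exactly the bookkeeping a rebuild would produce", {
  g <- example_graph()
  st <- apply_link(clustering_state(g), "u", "v")
  expect_equal(st$deg[["u"]], 3)
  expect_equal(st$tri[["u"]], 1)
  expect_equal(st$C, 1 / 2)
  for (seed in 1:30) {
    gg <- random_named_graph(12 + (seed %% 5) * 8, 0.1, seed + 7000)
    cand <- all_missing_links(gg)
    if (nrow(cand) == 0) next
    i <- withr::with_seed(seed, sample.int(nrow(cand), 1))
    committed <- apply_link(clustering_state(gg), cand$u[i], cand$v[i])
    rebuilt <- clustering_state(plus_link(gg, cand$u[i], cand$v[i]))
    expect_equal(committed$deg, rebuilt$deg)
    expect_equal(committed$tri, rebuilt$tri)
    expect_equal(committed$local, rebuilt$local, tolerance = 1e-13)
    expect_equal(committed$C, rebuilt$C, tolerance = 1e-13)
    expect_equal(committed$adj, rebuilt$adj)
  }
})

test_that("linking two isolated nodes changes no triangle count", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- letters[1:4]
  st <- apply_link(clustering_state(g), "a", "b")
  expect_equal(unname(st$tri), rep(0, 4))
  expect_equal(st$C, 0)
})

test_that("the vectorized all-pairs scorer matches the scalar update", {
  for (seed in 1:20) {
    gg <- random_named_graph(10 + (seed %% 4) * 12, 0.05 + 0.08 * (seed %% 5),
                             seed + 5000)
    st <- clustering_state(gg)
    sc <- clustlink:::score_all_pairs(st)
    cand <- all_missing_links(gg)
    for (i in seq_len(nrow(cand))) {
      expect_equal(sc[cand$u[i], cand$v[i]],
                   updated_graph_clustering(st, cand$u[i], cand$v[i]),
                   tolerance = 1e-13)
    }
    expect_true(all(is.na(diag(sc))))
    expect_true(all(is.na(sc[st$adj > 0])))
  }
})
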