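test_that("read_edge_list deduplicates, drops self-loops, and validates input", {
  p <- tmp_text_file(c("# comment", "a\tb", "b\ta", "b\tc", ""))
  expect_warning(g <- read_edge_list(p), "duplicate")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::V(g)$name, c("a", "b", "c"))

  expect_equal(igraph::vcount(read_edge_list(tmp_text_file("# only comments"))), 0L)

  expect_warning(g2 <- read_edge_list(tmp_text_file(c("a a", "a b"))),
                 "self-loop")
  expect_equal(igraph::ecount(g2), 1L)

  expect_error(read_edge_list(tmp_text_file(c("a b", "c"))), "line 2")
  expect_error(read_edge_list(tmp_text_file("a b -1"), weighted = TRUE),
               "positive")
  gw <- read_edge_list(tmp_text_file(c("a b 2.5", "b c 0.5")), weighted = TRUE)
  expect_equal(sort(igraph::E(gw)$weight), c(0.5, 2.5))
})

test_that("largest_connected_component keeps the dominant component", {
  g <- make_interactome(c("a", "b", "c", "d", "x", "y"),
                        c("b", "c", "d", "e", "y", "z"))
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))

  conn <- make_interactome(c("a", "b"), c("b", "c"))
  expect_equal(igraph::V(largest_connected_component(conn))$name,
               igraph::V(conn)$name)

  # size tie broken toward the component holding the smallest label
  tie <- make_interactome(c("b", "a"), c("d", "c"))
  expect_setequal(igraph::V(largest_connected_component(tie))$name, c("a", "c"))

  expect_error(largest_connected_component(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("all_pairs_shortest_paths handles hops, weights and degenerate input", {
  g <- make_interactome(c("a", "b"), c("b", "c"))
  d <- all_pairs_shortest_paths(g)
  expect_equal(d["a", "c"], 2)
  expect_equal(diag(d), stats::setNames(rep(0, 3), c("a", "b", "c")))

  tri <- make_interactome(c("a", "b", "a"), c("b", "c", "c"), w = c(1, 1, 10))
  dw <- all_pairs_shortest_paths(tri, use_weights = TRUE)
  expect_equal(dw["a", "c"], 2)           # detour a-b-c beats the heavy edge
  expect_equal(all_pairs_shortest_paths(tri)["a", "c"], 1)  # unweighted ignores weights

  single <- make_interactome(character(0), character(0), extra_nodes = "a")
  expect_equal(all_pairs_shortest_paths(single), matrix(0, 1, 1, dimnames = list("a", "a")))

  disc <- make_interactome(c("a", "x"), c("b", "y"))
  expect_error(all_pairs_shortest_paths(disc), "largest_connected_component")
})

test_that("shortest paths match exhaustive enumeration and obey the triangle inequality", {
  set.seed(101)
  for (trial in 1:25) {
    g <- random_connected_graph(sample(4:7, 1), extra = sample(0:3, 1),
                                weighted = trial %% 2 == 0)
    use_w <- "weight" %in% igraph::edge_attr_names(g)
    d <- all_pairs_shortest_paths(g, use_weights = use_w)
    nodes <- igraph::V(g)$name
    pick <- t(combn(nodes, 2))[sample(choose(length(nodes), 2), 3), , drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      expect_equal(d[pick[k, 1], pick[k, 2]],
                   oracle_distance(g, pick[k, 1], pick[k, 2], use_w))
    }
    for (m in nodes) {
      expect_true(all(d <= outer(d[, m], d[m, ], `+`) + 1e-12))
    }
  }
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  g <- make_interactome(c("a", "b"), c("b", "c"))
  expect_equal(betweenness_centrality(g),
               stats::setNames(c(0, 1, 0), c("a", "b", "c")))
  star <- make_interactome(c("h", "h", "h"), c("l1", "l2", "l3"))
  bc <- betweenness_centrality(star)
  expect_equal(bc[["h"]], 3)
  expect_equal(unname(bc[c("l1", "l2", "l3")]), rep(0, 3))

  set.seed(202)
  for (trial in 1:10) {
    g <- random_connected_graph(sample(5:8, 1), extra = sample(0:3, 1))
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-12)
  }
})

test_that("average_degree averages interactome degrees of the listed genes", {
  g <- make_interactome(c("a", "b"), c("b", "c"))
  expect_equal(average_degree(g, c("a", "b")), 1.5)
  star <- make_interactome(c("h", "h", "h"), c("l1", "l2", "l3"))
  expect_equal(average_degree(star, c("h", "l1")), 2)
  expect_error(average_degree(g, character(0)), "empty")
  expect_error(average_degree(g, "zz"), "zz")
})

test_that("minimum spanning tree is exact and deterministically tie-broken", {
  tri <- make_interactome(c("a", "b", "a"), c("b", "c", "c"), w = c(1, 1, 10))
  tr <- minimum_spanning_tree(tri)
  expect_equal(igraph::ecount(tr), 2L)
  expect_equal(sum(igraph::E(tr)$weight), 2)
  el <- igraph::as_edgelist(tr)
  expect_setequal(paste(el[, 1], el[, 2]), c("a b", "b c"))

  # a tree is its own MST
  tree <- make_interactome(c("a", "b", "b"), c("b", "c", "d"), w = c(1, 2, 3))
  trt <- minimum_spanning_tree(tree)
  expect_equal(igraph::ecount(trt), 3L)
  expect_equal(sum(igraph::E(trt)$weight), 6)

  set.seed(303)
  for (trial in 1:20) {
    g <- random_connected_graph(sample(4:7, 1), extra = sample(1:3, 1),
                                weighted = TRUE)
    tr <- minimum_spanning_tree(g)
    expect_equal(igraph::ecount(tr), igraph::vcount(g) - 1L)
    expect_true(igraph::is_connected(tr))
    expect_equal(sum(igraph::E(tr)$weight), oracle_mst_weight(g))
    # independent cross-check against igraph's Prim implementation
    expect_equal(sum(igraph::E(tr)$weight),
                 sum(igraph::E(igraph::mst(g))$weight))
  }
})

test_that("pathway edge weights follow w = 1/(1+freq) and preserve unweighted MST under uniform annotation", {
  g <- make_interactome(c("a", "b", "c"), c("b", "c", "d"))
  ann <- list(p1 = c("a", "b", "c"), p2 = c("a", "b"), p3 = c("a", "b", "x"))
  gw <- pathway_edge_weights(g, ann)
  wl <- edge_weight_lookup(gw)
  expect_equal(wl[["a b"]], 1 / 4)   # co-occur in p1, p2, p3
  expect_equal(wl[["b c"]], 1 / 2)   # p1 only
  expect_equal(wl[["c d"]], 1)       # never co-occur
  expect_true(wl[["a b"]] < wl[["b c"]])

  # uniform frequency leaves the MST identical to the unweighted one
  set.seed(404)
  g2 <- random_connected_graph(6, extra = 3)
  nodes <- igraph::V(g2)$name
  uni <- list(all1 = nodes, all2 = nodes)
  t_u <- igraph::as_edgelist(minimum_spanning_tree(g2))
  t_w <- igraph::as_edgelist(minimum_spanning_tree(pathway_edge_weights(g2, uni)))
  expect_equal(paste(t_u[, 1], t_u[, 2]), paste(t_w[, 1], t_w[, 2]))
})

test_that("GMT round-trip preserves pathway sets", {
  ann <- list(pw1 = c("a", "b", "c"), pw2 = c("d", "e"))
  p <- tempfile(fileext = ".gmt")
  write_gmt(ann, p)
  expect_equal(read_gmt(p), ann)
  expect_error(read_gmt(tmp_text_file("pw1\tdesc")), "malformed")
})
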