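named_graph <- function(...) {
  g <- igraph::make_graph(...)
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("v", seq_len(igraph::vcount(g))))
  g
}

test_that("node path length and closeness match hand computations", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(apl_node(p4, "a"), 1.5)        # (0+1+2+3)/4
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  expect_equal(apl_node(tri, "b"), 2 / 3)     # (0+1+1)/3
  p3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(cc_node(p3, "b"), 1.0)
  expect_equal(cc_node(p3, "a"), 2 / 3)
  k5 <- igraph::make_full_graph(5)
  k5 <- igraph::set_vertex_attr(k5, "name", value = letters[1:5])
  expect_equal(cc_node(k5, "c"), 1.0)
  iso <- p3 + igraph::vertex("z")
  expect_equal(apl_node(iso, "z"), 0)
  expect_equal(cc_node(iso, "z"), 0)
  expect_error(apl_node(p4, "q"), "unknown node")
  expect_error(cc_node(p4, "q"), "unknown node")
})

test_that("network path length follows the connected-pairs convention", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(apl_net(p4), 5 / 3)
  two_edges <- igraph::make_graph(~ a - b, c - d)
  expect_equal(apl_net(two_edges), 1.0)  # only within-component pairs count
  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  expect_true(is.na(apl_net(edgeless)))
  expect_error(apl_net(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("clustering matches triangle enumeration on the paw graph", {
  paw <- igraph::make_graph(~ a - b, b - c, c - a, a - d)
  expect_equal(clustering_node(paw, "a"), 1 / 3)
  expect_equal(clustering_node(paw, "b"), 1)
  expect_equal(clustering_node(paw, "d"), 0)
  expect_equal(cc_net(paw), 7 / 12)
  star <- igraph::make_star(4, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name", value = letters[1:4])
  expect_equal(clustering_node(star, "a"), 0)
  expect_error(clustering_node(paw, "q"), "unknown node")
})

test_that("closed forms hold: complete graphs, paths and trees", {
  for (n in c(3, 5, 8)) {
    kn <- igraph::set_vertex_attr(igraph::make_full_graph(n), "name",
                                  value = paste0("k", seq_len(n)))
    expect_equal(apl_net(kn), 1.0)
    expect_equal(cc_net(kn), 1.0)
  }
  for (n in 3:10) {
    pn <- igraph::set_vertex_attr(igraph::make_ring(n, circular = FALSE),
                                  "name", value = paste0("p", seq_len(n)))
    expect_equal(apl_net(pn), (n + 1) / 3, tolerance = 1e-12)
    expect_equal(cc_net(pn), 0)
  }
  tree <- igraph::set_vertex_attr(igraph::make_tree(15, 2, "undirected"),
                                  "name", value = paste0("t", 1:15))
  expect_equal(cc_net(tree), 0)
})

test_that("all indicators match brute-force oracles on random graphs", {
  for (s in 1:30) {
    g <- random_test_graph(n = sample(4:30, 1), seed = s)
    adj <- adj_list(g)
    topo <- node_topology(g)
    for (i in seq_len(nrow(topo))) {
      v <- topo$node[i]
      expect_equal(topo$apl_node[i], oracle_apl_node(adj, v), tolerance = 1e-12)
      expect_equal(topo$cc_node[i], oracle_cc_node(adj, v), tolerance = 1e-12)
      expect_equal(topo$clustering[i], oracle_clustering_node(adj, v),
                   tolerance = 1e-12)
    }
    expect_equal(apl_net(g), oracle_apl_net(adj), tolerance = 1e-12)
    expect_equal(cc_net(g), oracle_cc_net(adj), tolerance = 1e-12)
  }
})

test_that("adding an edge never lengthens average paths in a connected graph", {
  for (s in 1:10) {
    g <- withr::with_seed(s, {
      g0 <- igraph::sample_gnp(12, 0.3)
      while (!igraph::is_connected(g0)) g0 <- igraph::sample_gnp(12, 0.3)
      igraph::set_vertex_attr(g0, "name", value = paste0("n", 1:12))
    })
    miss <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                    upper.tri(diag(12)), arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[1, ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]))
    expect_lte(apl_net(g2), apl_net(g))
  }
})

test_that("network topology summaries expose fragmentation", {
  two_comp <- igraph::make_graph(~ a - b, b - c, d - e)
  topo <- network_topology(two_comp)
  expect_equal(topo$n_components, 2L)
  expect_equal(topo$lcc_size, 3L)
  expect_equal(topo$n_nodes, 5L)
  expect_equal(topo$n_edges, 3L)
  empty <- network_topology(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(empty$n_nodes, 0L)
  expect_true(is.na(empty$apl_net))
})
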