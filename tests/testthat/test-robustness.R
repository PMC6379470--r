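test_that("attack removes targets and forms after/before quotients", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  res <- attack(p4, "b")
  expect_equal(res$removed, "b")
  expect_setequal(setdiff(letters[1:4], res$removed), c("a", "c", "d"))
  expect_equal(res$after$n_nodes, 3L)
  expect_equal(res$after$n_edges, 1L)
  expect_equal(res$after$apl_net, 1.0)
  expect_equal(res$ri_apl, 0.6)             # 1 / (5/3)
  expect_equal(res$pct_change_apl, -40)

  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  tri_res <- attack(tri, "a")
  expect_equal(tri_res$after$apl_net, 1.0)
  expect_equal(tri_res$after$cc_net, 0.0)
  expect_equal(tri_res$ri_cc, 0.0)
})

test_that("the empty attack is the exact identity", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  res <- attack(p4, character())
  expect_identical(res$ri_apl, 1)
  expect_identical(res$ri_cc, 1)
  expect_equal(res$before$n_nodes, res$after$n_nodes)
})

test_that("an attack that empties the graph reports undefined quotients", {
  edge <- igraph::make_graph(~ a - b)
  res <- attack(edge, c("a", "b"))
  expect_equal(res$after$n_nodes, 0L)
  expect_true(is.na(res$ri_apl))
  expect_true(is.na(res$ri_cc))
})

test_that("attacked-vs-other node comparison uses Welch t on both metrics", {
  # two well-separated components: a tight clique and a long path
  g <- igraph::make_graph(~ a - b, b - c, c - a, a - d, b - d, c - d,
                          p - q, q - r, r - s, s - t, t - u)
  res <- compare_attacked_nodes(g, c("a", "b", "c", "d"))
  expect_lt(res$p_apl, 0.01)
  expect_lt(res$p_cc, 0.01)
  expect_equal(res$n_attacked, 4L)
  topo <- node_topology(g)
  att <- topo$node %in% c("a", "b", "c", "d")
  expect_equal(res$p_apl,
               oracle_welch_p(topo$apl_node[att], topo$apl_node[!att]),
               tolerance = 1e-12)
  expect_error(compare_attacked_nodes(g, "a"), "insufficient group size")
})

test_that("identical attacked and other groups give p = 1", {
  # perfectly symmetric ring: every node has the same topology
  ring <- igraph::set_vertex_attr(igraph::make_ring(6), "name",
                                  value = letters[1:6])
  res <- compare_attacked_nodes(ring, c("a", "d"))
  expect_equal(res$p_apl, 1)
  expect_equal(res$p_cc, 1)
})

test_that("the null ensemble preserves counts and is seed-determined", {
  g <- random_test_graph(20, seed = 3, p = 0.25)
  targets <- igraph::V(g)$name[1:4]
  null1 <- generate_null(g, targets, n_replicates = 10, seed = 42)
  null2 <- generate_null(g, targets, n_replicates = 10, seed = 42)
  expect_identical(null1, null2)
  expect_length(null1$ri_apl$values, 10L)
  expect_length(null1$ri_cc$values, 10L)
  diff_seed <- generate_null(g, targets, n_replicates = 10, seed = 43)
  expect_false(identical(null1$ri_apl$values, diff_seed$ri_apl$values))

  none <- generate_null(g, character(), n_replicates = 5, seed = 1)
  expect_true(all(none$ri_apl$values == 1))
  expect_true(all(none$ri_cc$values == 1))
  expect_error(generate_null(g, targets, n_replicates = 0, seed = 1),
               ">= 1")
})

test_that("permutation p uses the add-one estimator and 95% band", {
  null <- list(values = as.numeric(1:1000), n_replicates = 1000L)
  above <- permutation_p(2000, null, "greater")
  expect_equal(above$p, 1 / 1001)
  expect_true(above$outside_95ci)
  below <- permutation_p(-5, null, "greater")
  expect_equal(below$p, 1.0)
  at_median <- permutation_p(500, null, "two_sided")
  expect_gt(at_median$p, 0.99)
  expect_false(at_median$outside_95ci)
  less <- permutation_p(0, null, "less")
  expect_equal(less$p, 1 / 1001)
  with_na <- list(values = c(NA, 1, 2, 3), n_replicates = 4L)
  res <- permutation_p(10, with_na, "greater")
  expect_equal(res$n_used, 3L)
  expect_equal(res$n_undefined, 1L)
  expect_equal(res$p, 1 / 4)
  expect_error(permutation_p(NA_real_, null), "undefined")
})

test_that("the robustness stage is a pure function of network, targets and seed", {
  g <- random_test_graph(25, seed = 9, p = 0.2)
  targets <- igraph::V(g)$name[1:5]
  a1 <- assess_robustness(g, targets, n_replicates = 30, seed = 7)
  a2 <- assess_robustness(g, targets, n_replicates = 30, seed = 7)
  expect_identical(a1, a2)
  expect_equal(a1$null$ri_apl$n_replicates, 30L)
})

fake_assessment <- function(ri_apl, ri_cc, out_apl, out_cc) {
  list(attack = list(before = list(n_nodes = 50L, n_edges = 100L),
                     removed = c("X", "Y"),
                     ri_apl = ri_apl, ri_cc = ri_cc,
                     pct_change_apl = (ri_apl - 1) * 100,
                     pct_change_cc = (ri_cc - 1) * 100),
       node_comparison = NULL,
       null = list(ri_apl = list(n_undefined = 0L),
                   ri_cc = list(n_undefined = 0L)),
       p_apl = list(p = if (out_apl) 0.001 else 0.4, outside_95ci = out_apl),
       p_cc = list(p = if (out_cc) 0.001 else 0.4, outside_95ci = out_cc),
       n_replicates = 1000L, seed = 1L)
}

test_that("the positioning verdict requires a unique doubly-significant compartment", {
  hit <- fake_assessment(1.4, 0.7, TRUE, TRUE)
  miss <- fake_assessment(1.02, 0.99, FALSE, FALSE)
  expect_equal(position_drug(list(glom = hit, tub = miss))$verdict, "glom")
  expect_equal(position_drug(list(glom = hit, tub = hit))$verdict,
               "inconclusive")
  expect_equal(position_drug(list(glom = miss, tub = miss))$verdict,
               "inconclusive")
  # significant but stabilizing (shorter paths) does not qualify
  stab <- fake_assessment(0.8, 0.7, TRUE, TRUE)
  expect_equal(position_drug(list(glom = stab, tub = miss))$verdict,
               "inconclusive")
  expect_error(position_drug(list(only = hit)), "2 compartments")
  report <- position_drug(list(glom = hit, tub = miss))
  expect_equal(report$compartments$tub$perm_p_apl, 0.4)
  expect_false(report$compartments$tub$outside_95ci_apl)
})
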