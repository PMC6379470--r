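test_that("planted DE counts, truth sets and determinism follow the config", {
  cfg <- synthetic_config(n_genes = 100, de_fraction = 0.1, seed = 1)
  sim <- simulate_expression(cfg)
  expect_length(sim$up_genes, 5L)
  expect_length(sim$down_genes, 5L)
  expect_equal(dim(sim$matrix$values), c(100L, 15L + 27L))
  sim2 <- simulate_expression(cfg)
  expect_identical(sim$matrix$values, sim2$matrix$values)

  none <- simulate_expression(synthetic_config(n_genes = 50, de_fraction = 0,
                                               seed = 2))
  expect_length(none$up_genes, 0L)
  expect_length(none$down_genes, 0L)
})

test_that("planted genes shift case means by the configured fold", {
  cfg <- synthetic_config(n_genes = 400, de_fraction = 0.1, de_fold = 4,
                          noise_sd = 0.1, seed = 3)
  sim <- simulate_expression(cfg)
  v <- sim$matrix$values
  case <- sim$matrix$group_labels == "case"
  lfc <- rowMeans(log(v[, case])) - rowMeans(log(v[, !case]))
  expect_true(all(lfc[sim$up_genes] > log(2)))
  expect_true(all(lfc[sim$down_genes] < -log(2)))
  bg <- setdiff(rownames(v), c(sim$up_genes, sim$down_genes))
  expect_lt(max(abs(lfc[bg])), log(2))
})

test_that("gnm interaction tables have the exact node and edge counts", {
  cfg <- synthetic_config(n_genes = 100, n_net_nodes = 50, n_net_edges = 120,
                          net_model = "gnm", seed = 4)
  uni <- sprintf("U%03d", 1:100)
  tab <- simulate_interactions(cfg, uni)
  expect_equal(nrow(tab), 120L)
  expect_equal(length(unique(c(tab$gene_a, tab$gene_b))), 50L)
  expect_true(all(tab$confidence >= 0 & tab$confidence <= 1))
  expect_identical(tab, simulate_interactions(cfg, uni))
  # the low-confidence mixture component exercises the 0.4 filter
  expect_gt(sum(tab$confidence < 0.4), 0L)
  expect_gt(sum(tab$confidence > 0.4), 0L)
})

test_that("preferential attachment yields heavier-tailed degrees than gnm", {
  uni <- sprintf("U%03d", 1:120)
  wins <- vapply(1:50, function(s) {
    cfg_pa <- synthetic_config(n_genes = 120, n_net_nodes = 100,
                               n_net_edges = 297,
                               net_model = "preferential_attachment",
                               pa_edges_per_node = 3, seed = s)
    cfg_gnm <- synthetic_config(n_genes = 120, n_net_nodes = 100,
                                n_net_edges = 297, net_model = "gnm",
                                seed = s)
    max_deg <- function(tab) {
      g <- igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE)
      max(igraph::degree(g))
    }
    max_deg(simulate_interactions(cfg_pa, uni)) >=
      max_deg(simulate_interactions(cfg_gnm, uni))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("target sampling is uniform at hub_bias 0 and hub-seeking at high bias", {
  tab <- star_interactions(9)  # 10 nodes, center degree 9
  cfg0 <- synthetic_config(n_genes = 10, de_fraction = 0, n_net_nodes = 10,
                           n_net_edges = 9, n_targets = 2, hub_bias = 0,
                           seed = 1)
  hits <- vapply(1:2000, function(s)
    "HUB0" %in% simulate_drug_targets(cfg0, tab, seed = s), logical(1))
  p_hat <- mean(hits)
  # exact binomial: P(center drawn) = n_targets / n = 0.2
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(p_hat - 0.2), 3 * se)

  cfg5 <- synthetic_config(n_genes = 10, de_fraction = 0, n_net_nodes = 10,
                           n_net_edges = 9, n_targets = 1, hub_bias = 5,
                           seed = 1)
  hits5 <- vapply(1:1000, function(s)
    "HUB0" %in% simulate_drug_targets(cfg5, tab, seed = s), logical(1))
  # center weight 9^5 vs 9 leaves at weight 1: selection is near-certain
  expect_gt(mean(hits5), 0.99)

  cfg_all <- synthetic_config(n_genes = 10, de_fraction = 0, n_net_nodes = 10,
                              n_net_edges = 9, n_targets = 10, seed = 1)
  expect_setequal(simulate_drug_targets(cfg_all, tab),
                  c("HUB0", sprintf("LEAF%02d", 1:9)))
  expect_error(simulate_drug_targets(
    synthetic_config(n_genes = 10, de_fraction = 0, n_net_nodes = 10,
                     n_net_edges = 9, n_targets = 11, seed = 1), tab),
    "n_targets")
})

test_that("two-compartment studies share the configured fraction of planted genes", {
  cfg <- synthetic_config(n_genes = 500, de_fraction = 0.1,
                          n_net_nodes = 120, n_net_edges = 360, seed = 7)
  study <- simulate_study(cfg, overlap_fraction = 0.4)
  planted_a <- c(study$expression$A$up_genes, study$expression$A$down_genes)
  planted_b <- c(study$expression$B$up_genes, study$expression$B$down_genes)
  expect_length(planted_b, length(planted_a))
  expect_gte(length(intersect(planted_a, planted_b)),
             round(0.4 * length(planted_a)))
  # every planted gene is covered by its compartment's interaction network
  expect_true(all(planted_a %in%
                    c(study$interactions$A$gene_a, study$interactions$A$gene_b)))
  expect_true(all(planted_b %in%
                    c(study$interactions$B$gene_a, study$interactions$B$gene_b)))
  # deterministic under the same config
  study2 <- simulate_study(cfg, overlap_fraction = 0.4)
  expect_identical(study$targets, study2$targets)
  expect_identical(study$expression$B$matrix$values,
                   study2$expression$B$matrix$values)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_net_nodes = 10, n_net_edges = 46),
               "infeasible")
  expect_error(synthetic_config(n_genes = 5, de_fraction = 0.01), "DE gene")
  expect_error(synthetic_config(de_fold = 1), "de_fold")
  expect_error(simulate_interactions(
    synthetic_config(n_genes = 10, de_fraction = 0, n_net_nodes = 10,
                     n_net_edges = 9),
    sprintf("U%d", 1:5)), "universe")
})
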