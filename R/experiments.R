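# Seeded simulation experiments at study conditions. These are the
# package's own validation studies: null-model calibration, recovery of a
# hub-directed (planted) drug attack, and recovery of planted DE genes.
# The tests and the reproduction script both call these, so the measured
# numbers always come from the same code path.

#' Calibration of the permutation p-value under the null
#'
#' Draws the "observed" network itself from the uniform fixed-node/edge
#' ensemble and attacks a fixed random node set, so the permutation
#' p-value for the path-length quotient should be approximately uniform:
#' the fraction of seeds with p < 0.05 should sit near 0.05.
#'
#' @param n_seeds Number of independent observed networks.
#' @param n_nodes,n_edges Network size for each draw.
#' @param n_targets Attacked-set size.
#' @param n_null Null replicates per observed network.
#' @param seed Master seed.
#' @return Numeric vector of `n_seeds` permutation p-values (upper tail
#'   of `ri_apl`).
#' @export
null_calibration_experiment <- function(n_seeds = 200, n_nodes = 60,
                                        n_edges = 150, n_targets = 10,
                                        n_null = 200, seed = 1) {
  vapply(seq_len(n_seeds), function(s) {
    base <- sub_seed(seed, 7000L + s)
    labels <- sprintf("N%03d", seq_len(n_nodes))
    g <- withr::with_seed(base, {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      igraph::set_vertex_attr(g, "name", value = labels)
    })
    targets <- withr::with_seed(sub_seed(base, 1L),
                                sample(labels, n_targets))
    att <- attack(g, targets)
    null <- generate_null(g, targets, n_replicates = n_null,
                          seed = sub_seed(base, 2L))
    permutation_p(att$ri_apl, null$ri_apl, "greater")$p
  }, numeric(1))
}

#' Recovery of a planted hub-directed attack across two compartments
#'
#' For each seed, two matched scale-free (preferential-attachment)
#' compartment networks are generated; the drug's targets are drawn
#' hub-biased (`hub_bias[1]`) in compartment A and uniformly
#' (`hub_bias[2] = 0`) in compartment B. A positioning method should
#' find A's attack more destabilizing: its upper-tail permutation p for
#' the path-length quotient smaller than B's, and A flagged outside the
#' null's 95% band.
#'
#' @param n_seeds Number of replicate studies.
#' @param n_nodes Nodes per compartment network.
#' @param pa_edges_per_node Preferential-attachment edges per node
#'   (3 with 250 nodes gives ~750 edges).
#' @param n_targets Targets drawn per compartment.
#' @param hub_bias Length-2: degree exponent for compartments A and B.
#' @param n_null Null replicates per assessment.
#' @param seed Master seed.
#' @return A `data.frame` with one row per seed: `p_apl_a`, `p_apl_b`,
#'   `p_cc_a`, `p_cc_b`, `outside_ci_a`, `outside_ci_b`,
#'   `ri_apl_a`, `ri_apl_b`.
#' @export
planted_positioning_experiment <- function(n_seeds = 50, n_nodes = 250,
                                           pa_edges_per_node = 3,
                                           n_targets = 20,
                                           hub_bias = c(3, 0),
                                           n_null = 500, seed = 1) {
  universe <- sprintf("G%04d", seq_len(n_nodes))
  one_side <- function(base, bias, off) {
    cfg <- synthetic_config(n_genes = n_nodes, n_net_nodes = n_nodes,
                            n_net_edges = pa_edges_per_node * (n_nodes - 1),
                            net_model = "preferential_attachment",
                            pa_edges_per_node = pa_edges_per_node,
                            low_conf_fraction = 0, n_targets = n_targets,
                            hub_bias = bias, seed = base)
    ints <- simulate_interactions(cfg, universe, seed = sub_seed(base, off))
    targets <- simulate_drug_targets(cfg, ints, seed = sub_seed(base, off + 1L))
    net <- build_network(unique(c(ints$gene_a, ints$gene_b)), ints,
                         min_confidence = 0.4)
    assess_robustness(net, targets, n_replicates = n_null,
                      seed = sub_seed(base, off + 2L))
  }
  rows <- lapply(seq_len(n_seeds), function(s) {
    base <- sub_seed(seed, 8000L + s)
    a <- one_side(base, hub_bias[1L], 10L)
    b <- one_side(base, hub_bias[2L], 20L)
    data.frame(p_apl_a = a$p_apl$p, p_apl_b = b$p_apl$p,
               p_cc_a = a$p_cc$p, p_cc_b = b$p_cc$p,
               outside_ci_a = a$p_apl$outside_95ci,
               outside_ci_b = b$p_apl$outside_95ci,
               ri_apl_a = a$attack$ri_apl, ri_apl_b = b$attack$ri_apl)
  })
  do.call(rbind, rows)
}

#' Recovery of planted differentially expressed genes
#'
#' Simulates case/control matrices at the study's sample sizes and scores
#' the DEG filter against the planted truth: sensitivity is the fraction
#' of planted genes called with the correct direction; the
#' wrong-direction rate is the fraction of planted genes that are called
#' but with the opposite direction.
#'
#' @param n_seeds Number of simulated matrices.
#' @param config A [synthetic_config()] defining sample sizes, effect and
#'   noise.
#' @param seed Master seed.
#' @return A `data.frame` with one row per seed: `sensitivity`,
#'   `wrong_direction_rate`, `n_planted`, `n_called`.
#' @export
deg_recovery_experiment <- function(n_seeds = 20,
                                    config = synthetic_config(
                                      n_genes = 1000, de_fraction = 0.05,
                                      de_fold = 1.5, noise_sd = 0.3),
                                    seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_expression(config, seed = sub_seed(seed, 9000L + s))
    degs <- call_degs(sim$matrix)
    up_called <- degs$gene[degs$direction == "up"]
    down_called <- degs$gene[degs$direction == "down"]
    planted <- c(sim$up_genes, sim$down_genes)
    correct <- length(intersect(sim$up_genes, up_called)) +
      length(intersect(sim$down_genes, down_called))
    wrong <- length(intersect(sim$up_genes, down_called)) +
      length(intersect(sim$down_genes, up_called))
    called_planted <- correct + wrong
    data.frame(sensitivity = correct / length(planted),
               wrong_direction_rate = if (called_planted) wrong / called_planted else 0,
               n_planted = length(planted),
               n_called = length(c(up_called, down_called)))
  })
  do.call(rbind, rows)
}
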