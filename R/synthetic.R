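# Synthetic-data generator: expression matrices with planted DE genes,
# confidence-scored interaction networks (uniform G(n,m) or preferential
# attachment) and hub-biased drug-target sets. Every generator is a pure
# function of its config and seed, so the whole downstream pipeline is
# testable without any external download.

#' Synthetic study configuration
#'
#' Defaults mirror a two-compartment kidney-biopsy microarray study: 15
#' case vs 27 control samples, log-normal expression noise, a sparse
#' planted DE fraction, and a scale-free interaction network dense
#' enough that the DEG-induced disease network reaches the mean degree
#' (~7) typical of curated interactions among co-regulated genes.
#'
#' @param n_genes Number of genes in the expression universe.
#' @param n_case,n_control Samples per group.
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed (split evenly up/down).
#' @param de_fold Linear fold change applied to planted genes in cases
#'   (> 1; down-genes are divided by it).
#' @param noise_sd Standard deviation of Gaussian noise on the natural
#'   log scale.
#' @param n_net_nodes,n_net_edges Interaction-network size. For the
#'   preferential-attachment model the edge count is determined by
#'   `pa_edges_per_node` and `n_net_edges` is treated as approximate.
#' @param net_model `"gnm"` (uniform fixed node/edge counts) or
#'   `"preferential_attachment"`.
#' @param pa_edges_per_node Edges added per new node in the
#'   preferential-attachment model.
#' @param low_conf_fraction Fraction of edges assigned a confidence below
#'   0.4, exercising the confidence filter.
#' @param n_targets Drug-target set size.
#' @param hub_bias Exponent on node degree when sampling targets; 0 is
#'   uniform, larger values concentrate targets on hubs.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_case = 15, n_control = 27,
                             de_fraction = 0.05, de_fold = 1.5,
                             noise_sd = 0.3, n_net_nodes = 150,
                             n_net_edges = 894,
                             net_model = c("preferential_attachment", "gnm"),
                             pa_edges_per_node = 6,
                             low_conf_fraction = 0.25,
                             n_targets = 20, hub_bias = 0, seed = 1) {
  net_model <- match.arg(net_model)
  cfg <- list(n_genes = n_genes, n_case = n_case, n_control = n_control,
              de_fraction = de_fraction, de_fold = de_fold,
              noise_sd = noise_sd, n_net_nodes = n_net_nodes,
              n_net_edges = n_net_edges, net_model = net_model,
              pa_edges_per_node = pa_edges_per_node,
              low_conf_fraction = low_conf_fraction,
              n_targets = n_targets, hub_bias = hub_bias,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1 || n_case < 2 || n_control < 2)
      stop_input("need n_genes >= 1 and >= 2 samples per group")
    if (de_fraction < 0 || de_fraction > 1)
      stop_input("de_fraction must be in [0, 1]")
    if (de_fraction > 0 && de_fraction * n_genes < 1)
      stop_input("de_fraction * n_genes < 1: no DE gene can be planted")
    if (de_fold <= 1) stop_input("de_fold must be > 1")
    if (noise_sd <= 0) stop_input("noise_sd must be > 0")
    if (n_net_edges > n_net_nodes * (n_net_nodes - 1) / 2)
      stop_input("n_net_edges infeasible for n_net_nodes")
    if (hub_bias < 0) stop_input("hub_bias must be >= 0")
    if (low_conf_fraction < 0 || low_conf_fraction > 1)
      stop_input("low_conf_fraction must be in [0, 1]")
  })
  invisible(cfg)
}

#' Simulate a case/control expression matrix with planted DE genes
#'
#' Baseline expression is log-normal (gene-level log-means drawn once,
#' sample noise Gaussian on the log scale with sd `noise_sd`). A
#' `de_fraction` of genes is planted as differentially expressed: their
#' case-group mean is multiplied (up) or divided (down) by `de_fold`,
#' split evenly between directions.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return List with `matrix` (an [expression_matrix()]), `up_genes`,
#'   `down_genes` (the planted truth sets).
#' @export
simulate_expression <- function(config, seed = config$seed) {
  validate_config(config)
  withr::with_seed(sub_seed(seed, 101L), {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    n_de <- round(config$de_fraction * config$n_genes)
    de <- sample(genes, n_de)
    up <- de[seq_len(floor(n_de / 2))]
    down <- setdiff(de, up)
    base_log <- stats::rnorm(config$n_genes, mean = log(100), sd = 1)
    names(base_log) <- genes
    shift <- stats::setNames(rep(0, config$n_genes), genes)
    shift[up] <- log(config$de_fold)
    shift[down] <- -log(config$de_fold)
    n_s <- config$n_case + config$n_control
    labels <- rep(c("case", "control"), c(config$n_case, config$n_control))
    mu <- matrix(base_log, config$n_genes, n_s)
    mu[, labels == "case"] <- mu[, labels == "case"] + shift
    noise <- matrix(stats::rnorm(config$n_genes * n_s, sd = config$noise_sd),
                    config$n_genes, n_s)
    vals <- exp(mu + noise)
    colnames(vals) <- sprintf("S%02d_%s", seq_len(n_s), labels)
    rownames(vals) <- genes
    list(matrix = expression_matrix(vals, labels),
         up_genes = sort(up), down_genes = sort(down))
  })
}

#' Simulate a confidence-scored interaction table
#'
#' Samples `n_net_nodes` genes from the universe (any `focus_genes` are
#' included first, so a planted DE set is guaranteed network coverage,
#' mirroring real disease networks where most DEGs carry curated
#' interactions), wires them with either a uniform G(n, m) graph or a
#' preferential-attachment (scale-free) graph, and assigns each edge a
#' confidence drawn from a two-component mixture: a `low_conf_fraction`
#' falls uniformly in (0.05, 0.4) and the rest uniformly in (0.4, 1), so
#' the standard 0.4 filter is exercised.
#'
#' @param config A [synthetic_config()].
#' @param gene_universe Character vector of available gene symbols.
#' @param focus_genes Genes to include in the network node set first.
#' @param seed Optional seed override.
#' @return A cleaned interaction table (`gene_a`, `gene_b`, `confidence`).
#' @export
simulate_interactions <- function(config, gene_universe,
                                  focus_genes = character(),
                                  seed = config$seed) {
  validate_config(config)
  gene_universe <- norm_symbols(gene_universe)
  focus_genes <- intersect(norm_symbols(focus_genes), gene_universe)
  if (config$n_net_nodes > length(gene_universe))
    stop_input("n_net_nodes exceeds the gene universe")
  withr::with_seed(sub_seed(seed, 202L), {
    pool <- setdiff(gene_universe, focus_genes)
    n_fill <- config$n_net_nodes - min(length(focus_genes), config$n_net_nodes)
    nodes <- c(utils::head(focus_genes, config$n_net_nodes),
               sample(pool, n_fill))
    g <- if (config$net_model == "gnm") {
      igraph::sample_gnm(config$n_net_nodes, config$n_net_edges)
    } else {
      igraph::sample_pa(config$n_net_nodes, m = config$pa_edges_per_node,
                        directed = FALSE)
    }
    # random node relabelling so focus genes are not confounded with the
    # preferential-attachment arrival order
    g <- igraph::set_vertex_attr(g, "name", value = sample(nodes))
    el <- igraph::as_edgelist(g, names = TRUE)
    n_e <- nrow(el)
    low <- stats::runif(n_e) < config$low_conf_fraction
    conf <- ifelse(low, stats::runif(n_e, 0.05, 0.4),
                   stats::runif(n_e, 0.4000001, 1))
    interaction_table(el[, 1L], el[, 2L], conf, score_scale = "unit")
  })
}

#' Simulate a drug-target gene set with tunable hub bias
#'
#' Samples `n_targets` network nodes without replacement with selection
#' weight proportional to `degree^hub_bias` (computed on the full
#' interaction graph, before any confidence filtering). `hub_bias = 0`
#' is uniform sampling; large values make the drug a hub-directed attack.
#'
#' @param config A [synthetic_config()].
#' @param interactions An interaction table from
#'   [simulate_interactions()].
#' @param seed Optional seed override.
#' @return Character vector of target gene symbols.
#' @export
simulate_drug_targets <- function(config, interactions, seed = config$seed) {
  validate_config(config)
  g <- igraph::graph_from_data_frame(
    interactions[, c("gene_a", "gene_b")], directed = FALSE)
  nodes <- igraph::V(g)$name
  if (config$n_targets > length(nodes))
    stop_input("n_targets exceeds the number of network nodes")
  deg <- igraph::degree(g)
  w <- if (config$hub_bias == 0) rep(1, length(nodes)) else deg^config$hub_bias
  withr::with_seed(sub_seed(seed, 303L),
    sort(sample(nodes, config$n_targets, prob = w)))
}

#' Simulate a full two-compartment study
#'
#' One gene universe; per-compartment expression matrices whose planted
#' DE sets overlap by `overlap_fraction`; per-compartment interaction
#' tables whose node sets cover the respective planted DE genes; and one
#' drug-target set drawn from each compartment network with its own hub
#' bias, then merged. With `hub_bias = c(3, 0)` the drug is planted to
#' attack compartment A's hubs while hitting compartment B indifferently
#' — the configuration a positioning method must recover.
#'
#' @param config A [synthetic_config()]; `config$hub_bias` is ignored in
#'   favour of `hub_bias`.
#' @param overlap_fraction Fraction of compartment A's planted DE genes
#'   reused in compartment B.
#' @param hub_bias Length-2 numeric: target hub bias for compartments A
#'   and B.
#' @return List with `expression` (named list of
#'   `list(matrix, up_genes, down_genes)`), `interactions` (named list of
#'   tables), `targets` (merged gene set), `config`.
#' @export
simulate_study <- function(config = synthetic_config(),
                           overlap_fraction = 0.3,
                           hub_bias = c(3, 0)) {
  validate_config(config)
  stopifnot(length(hub_bias) == 2L, all(hub_bias >= 0))
  seed <- config$seed
  expr_a <- simulate_expression(config, seed = sub_seed(seed, 1L))
  expr_b <- simulate_expression(config, seed = sub_seed(seed, 2L))
  # overwrite part of B's planted set with A's so the compartments share
  # a controlled fraction of DE genes
  planted_a <- c(expr_a$up_genes, expr_a$down_genes)
  n_share <- round(overlap_fraction * length(planted_a))
  if (n_share > 0) {
    share <- withr::with_seed(sub_seed(seed, 3L), sample(planted_a, n_share))
    expr_b <- replant_genes(expr_b, intersect(share, expr_a$up_genes),
                            intersect(share, expr_a$down_genes), config)
  }
  universe <- expr_a$matrix$gene_ids
  int_a <- simulate_interactions(config, universe,
                                 focus_genes = c(expr_a$up_genes, expr_a$down_genes),
                                 seed = sub_seed(seed, 4L))
  int_b <- simulate_interactions(config, universe,
                                 focus_genes = c(expr_b$up_genes, expr_b$down_genes),
                                 seed = sub_seed(seed, 5L))
  cfg_a <- config; cfg_a$hub_bias <- hub_bias[1L]
  cfg_b <- config; cfg_b$hub_bias <- hub_bias[2L]
  t_a <- simulate_drug_targets(cfg_a, int_a, seed = sub_seed(seed, 6L))
  t_b <- simulate_drug_targets(cfg_b, int_b, seed = sub_seed(seed, 7L))
  list(expression = list(A = expr_a, B = expr_b),
       interactions = list(A = int_a, B = int_b),
       targets = sort(unique(c(t_a, t_b))),
       targets_by_compartment = list(A = t_a, B = t_b),
       config = config, overlap_fraction = overlap_fraction,
       hub_bias = stats::setNames(hub_bias, c("A", "B")))
}

# Re-plant a simulated matrix so that the shared genes (with compartment
# A's directions) replace an equal number of its own planted DE genes,
# keeping the total planted count fixed. Effects are adjusted
# multiplicatively on the case columns via de_fold^(desired - current).
replant_genes <- function(expr, add_up, add_down, config) {
  vals <- expr$matrix$values
  labels <- unname(expr$matrix$group_labels)
  case <- labels == "case"
  genes <- rownames(vals)
  current <- stats::setNames(rep(0, length(genes)), genes)
  current[expr$up_genes] <- 1
  current[expr$down_genes] <- -1
  planted <- c(expr$up_genes, expr$down_genes)
  # drop B-private planted genes to make room for the shared ones, keeping
  # the total planted count fixed (chance overlaps need no replacement)
  n_drop <- length(add_up) + length(add_down) -
    length(intersect(c(add_up, add_down), planted))
  droppable <- setdiff(planted, c(add_up, add_down))
  drop_b <- utils::head(droppable, n_drop)
  desired <- current
  desired[drop_b] <- 0
  desired[add_up] <- 1
  desired[add_down] <- -1
  delta <- desired - current
  adj <- names(delta)[delta != 0]
  for (g in adj) vals[g, case] <- vals[g, case] * config$de_fold^delta[g]
  list(matrix = expression_matrix(vals, labels),
       up_genes = sort(names(desired)[desired == 1]),
       down_genes = sort(names(desired)[desired == -1]))
}

#' Write a simulated study to disk
#'
#' Emits per-compartment expression TSVs and interaction tables, the
#' merged drug-target list and the planted truth sets, all through the
#' package's writers.
#'
#' @param study Output of [simulate_study()].
#' @param out_dir Directory to write into (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_study_files <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (k in names(study$expression)) {
    paths[[paste0("expression_", k)]] <- write_expression_matrix(
      study$expression[[k]]$matrix,
      file.path(out_dir, sprintf("expression_%s.tsv", k)))
    utils::write.table(study$interactions[[k]],
                       file.path(out_dir, sprintf("interactions_%s.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("interactions_", k)]] <-
      file.path(out_dir, sprintf("interactions_%s.tsv", k))
    paths[[paste0("truth_up_", k)]] <- write_gene_list(
      study$expression[[k]]$up_genes,
      file.path(out_dir, sprintf("truth_up_%s.txt", k)))
    paths[[paste0("truth_down_", k)]] <- write_gene_list(
      study$expression[[k]]$down_genes,
      file.path(out_dir, sprintf("truth_down_%s.txt", k)))
  }
  paths$targets <- write_gene_list(study$targets,
                                   file.path(out_dir, "drug_targets.txt"))
  # possibility-scored table in the shape read_drug_targets() consumes;
  # all planted targets score above the default cut of 20
  target_tab <- data.frame(compound = "synthetic_drug",
                           gene = study$targets, score = 50)
  paths$target_table <- file.path(out_dir, "drug_targets.tsv")
  utils::write.table(target_tab, paths$target_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
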