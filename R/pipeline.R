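# End-to-end orchestration: per compartment, DEG table -> disease network
# -> topology -> drug attack -> random-network null -> permutation
# p-values; then the cross-compartment positioning verdict. Every stage's
# output is written and every stochastic draw descends from the single
# config seed.

#' Assemble a pipeline configuration
#'
#' @param compartments Named list; each element a list with fields
#'   `expression` (TSV path or an [expression_matrix()]), `group_map`
#'   (named vector sample -> "case"/"control"; ignored when an object is
#'   given), `interactions` (TSV path or cleaned table) and optionally
#'   `score_scale` (`"unit"`/`"thousand"`).
#' @param targets Drug-target table path (read with [read_drug_targets()]
#'   at `target_min_score`) or a character vector of target genes.
#' @param min_confidence,fc_up,fc_down,p_max,hub_factor,target_min_score,n_null
#'   Stage thresholds; defaults are the conventional ones (interaction
#'   confidence > 0.4, fold change >= 1.1 up / <= 0.91 down, p < 0.05,
#'   hub degree > 2 x median, possibility score > 20, 1000-replicate null).
#' @param seed Single integer seed for the whole run.
#' @param out_dir Directory for intermediate artifacts and the report;
#'   `NULL` disables writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(compartments, targets,
                            min_confidence = 0.4, fc_up = 1.1,
                            fc_down = 0.91, p_max = 0.05,
                            hub_factor = 2.0, target_min_score = 20,
                            n_null = 1000, seed = 1, out_dir = NULL) {
  if (length(compartments) < 1L || is.null(names(compartments)))
    stop_input("compartments must be a non-empty named list")
  stopifnot(min_confidence >= 0, min_confidence <= 1,
            fc_down < 1, fc_up > 1, p_max > 0, p_max <= 1,
            hub_factor >= 0, n_null >= 1)
  structure(list(compartments = compartments, targets = targets,
                 min_confidence = min_confidence, fc_up = fc_up,
                 fc_down = fc_down, p_max = p_max,
                 hub_factor = hub_factor,
                 target_min_score = target_min_score,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: a `compartments` mapping (each
#' with `expression`, `group_map`, `interactions`, optional
#' `score_scale`), a `targets` path, and optional threshold overrides.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  comps <- lapply(y$compartments, function(cc) {
    cc$group_map <- unlist(cc$group_map)
    cc
  })
  args <- y[setdiff(names(y), c("compartments", "targets"))]
  do.call(pipeline_config,
          c(list(compartments = comps, targets = y$targets), args))
}

load_compartment <- function(cc, config) {
  mat <- if (inherits(cc$expression, "expression_matrix")) cc$expression
         else read_expression_matrix(cc$expression, cc$group_map)
  ints <- if (is.data.frame(cc$interactions)) cc$interactions
          else read_interaction_table(cc$interactions,
                 score_scale = if (is.null(cc$score_scale)) "unit"
                               else cc$score_scale)
  list(matrix = mat, interactions = ints)
}

#' Run the full drug-positioning pipeline
#'
#' For every compartment: differential expression, disease-network
#' assembly, hub and drug-target flagging, node-level comparison, drug
#' attack, random-network null and permutation p-values; then the
#' cross-compartment positioning verdict. When `config$out_dir` is set,
#' DEG tables, networks (GraphML), node-topology tables, the JSON report
#' and a run manifest are written there.
#'
#' @param config A [pipeline_config()].
#' @return The positioning report (see [position_drug()]) augmented with
#'   per-compartment DEG counts and parameters.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (cc in config$compartments)
    for (f in c("expression", "interactions"))
      if (is.character(cc[[f]]) && !file.exists(cc[[f]]))
        stop_input("input file not found: ", cc[[f]])
  targets <- if (is.character(config$targets) &&
                 length(config$targets) == 1L && file.exists(config$targets))
    read_drug_targets(config$targets, min_score = config$target_min_score)
  else norm_symbols(config$targets)

  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  assessments <- list()
  deg_tables <- list()
  n_hubs <- integer()
  for (i in seq_along(config$compartments)) {
    name <- names(config$compartments)[i]
    inputs <- load_compartment(config$compartments[[i]], config)
    degs <- call_degs(inputs$matrix, fc_up = config$fc_up,
                      fc_down = config$fc_down, p_max = config$p_max)
    deg_tables[[name]] <- degs
    net <- build_network(degs, inputs$interactions,
                         min_confidence = config$min_confidence)
    net <- flag_hubs(net, factor = config$hub_factor)
    flagged <- flag_drug_targets(net, targets)
    net <- flagged$network
    n_hubs[name] <- sum(igraph::V(net)$is_hub)
    assessments[[name]] <- assess_robustness(
      net, flagged$attacked, n_replicates = config$n_null,
      seed = sub_seed(config$seed, 1000L + i))
    if (!is.null(out)) {
      write_deg_table(degs, file.path(out, sprintf("degs_%s.tsv", name)))
      write_network(net, file.path(out, sprintf("network_%s.graphml", name)),
                    format = "graphml")
      utils::write.table(node_topology(net),
                         file.path(out, sprintf("topology_%s.tsv", name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report <- if (length(assessments) >= 2L) position_drug(assessments)
            else list(compartments = NULL, verdict = "inconclusive")
  for (name in names(assessments)) {
    report$compartments[[name]]$n_degs <-
      length(deg_genes(deg_tables[[name]]))
    report$compartments[[name]]$n_hubs <- n_hubs[[name]]
  }
  if (length(deg_tables) >= 2L) {
    venn <- compare_compartment_degs(deg_tables[[1L]], deg_tables[[2L]])
    report$deg_overlap <- list(
      only_first = length(venn$only_a), only_second = length(venn$only_b),
      shared = length(venn$shared))
  }
  report$parameters <- config[c("min_confidence", "fc_up", "fc_down",
                                "p_max", "hub_factor", "target_min_score",
                                "n_null", "seed")]
  report$n_targets_supplied <- length(targets)
  if (!is.null(out)) {
    write_report(report, file.path(out, "report.json"))
    write_report(list(package = "netrobust",
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."),
                      parameters = report$parameters,
                      compartments = names(config$compartments)),
                 file.path(out, "run_manifest.json"))
  }
  report
}
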