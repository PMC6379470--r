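# Disease-network assembly: induce the confidence-filtered interaction
# subgraph on the called DEGs, then flag hub and drug-attacked nodes.

#' Build a per-compartment disease network
#'
#' Nodes are called DEGs that retain at least one interaction with another
#' DEG at confidence strictly above `min_confidence`; DEGs with no passing
#' edge are excluded by default (set `keep_isolated = TRUE` to retain
#' them). The result is a simple undirected igraph with vertex attributes
#' `is_hub` and `is_drug_target` initialised to `FALSE`.
#'
#' @param degs A DEG table from [call_degs()], or a character vector of
#'   gene symbols.
#' @param interactions A cleaned interaction table
#'   (see [interaction_table()]).
#' @param min_confidence Keep edges with confidence strictly greater than
#'   this (default 0.4, the usual medium-confidence cut).
#' @param keep_isolated Retain DEGs without any passing edge as isolated
#'   nodes.
#' @param allow_empty If no edge passes, return an empty graph instead of
#'   raising an error.
#' @return An igraph object.
#' @export
build_network <- function(degs, interactions, min_confidence = 0.4,
                          keep_isolated = FALSE, allow_empty = FALSE) {
  genes <- if (is.data.frame(degs)) deg_genes(degs) else sort(norm_symbols(degs))
  if (length(genes) == 0L) stop_input("no nodes: empty DEG list")
  keep <- interactions$confidence > min_confidence &
    interactions$gene_a %in% genes & interactions$gene_b %in% genes
  el <- interactions[keep, c("gene_a", "gene_b"), drop = FALSE]
  if (nrow(el) == 0L && !keep_isolated && !allow_empty)
    stop_input("no interaction passes min_confidence = ", min_confidence,
               " among the DEGs (set allow_empty = TRUE for an empty network)")
  nodes <- if (keep_isolated) genes else sort(unique(c(el$gene_a, el$gene_b)))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  igraph::set_vertex_attr(igraph::set_vertex_attr(g, "is_hub", value = FALSE),
                          "is_drug_target", value = FALSE)
}

#' Flag hub nodes
#'
#' A hub is a node whose degree strictly exceeds `factor` times the median
#' degree over all nodes (midpoint convention for even node counts).
#'
#' @param network An igraph disease network.
#' @param factor Multiplier on the median degree (default 2).
#' @return The network with updated `is_hub` vertex attribute.
#' @export
flag_hubs <- function(network, factor = 2.0) {
  if (igraph::vcount(network) == 0L) stop_input("empty network")
  deg <- igraph::degree(network)
  igraph::set_vertex_attr(network, "is_hub",
                          value = deg > factor * stats::median(deg))
}

#' Extract the hub gene symbols
#' @param network An igraph network processed by [flag_hubs()].
#' @return Character vector of hub node names.
#' @export
hub_genes <- function(network) {
  sort(igraph::V(network)$name[igraph::V(network)$is_hub])
}

#' Flag drug-attacked nodes
#'
#' @param network An igraph disease network.
#' @param targets Character vector of drug-target gene symbols.
#' @return List with `network` (updated `is_drug_target` attribute) and
#'   `attacked` (the targets actually present in the network).
#' @export
flag_drug_targets <- function(network, targets) {
  present <- igraph::V(network)$name %in% norm_symbols(targets)
  list(network = igraph::set_vertex_attr(network, "is_drug_target",
                                         value = present),
       attacked = sort(igraph::V(network)$name[present]))
}
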