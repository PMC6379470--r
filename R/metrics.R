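# Topology indicators on unweighted, undirected disease networks.
#
# All shortest-path quantities follow a component convention: distance
# sums for a source node run over its connected component only, with the
# component size standing in for n, and the network-level average runs
# over connected ordered pairs. Drug attack can fragment a network, and
# this convention keeps every indicator well defined while reducing to
# the textbook formulas on connected graphs; the component count and
# largest-component size are always reported alongside so fragmentation
# stays visible.

#' Node average shortest-path length
#'
#' Mean of shortest-path distances from `source` to every node in its
#' connected component, including the zero self-distance, divided by the
#' component size. An isolated node scores 0.
#'
#' @param network An igraph undirected network with named vertices.
#' @param source A vertex name.
#' @return A non-negative real.
#' @export
apl_node <- function(network, source) {
  d <- source_distances(network, source)
  n_comp <- sum(is.finite(d))
  if (n_comp <= 1L) return(0)
  sum(d[is.finite(d)]) / n_comp
}

#' Node closeness centrality
#'
#' `(n - 1) / sum of distances` with `n` the size of the source's
#' connected component. An isolated node scores 0; on a complete graph
#' every node scores 1.
#'
#' @inheritParams apl_node
#' @return A real in `[0, 1]`.
#' @export
cc_node <- function(network, source) {
  d <- source_distances(network, source)
  n_comp <- sum(is.finite(d))
  if (n_comp <= 1L) return(0)
  (n_comp - 1) / sum(d[is.finite(d)])
}

source_distances <- function(network, source) {
  if (!source %in% igraph::V(network)$name)
    stop_input("unknown node: ", source)
  igraph::distances(network, v = source)[1L, ]
}

#' Network average shortest-path length
#'
#' Mean of `d(s, t)` over all ordered pairs of distinct, mutually
#' reachable nodes. Returns `NA` when no connected pair exists (the
#' undefined sentinel); errors on networks with fewer than 2 nodes.
#'
#' @param network An igraph undirected network.
#' @return A real >= 1, or `NA_real_` when no pair is connected.
#' @export
apl_net <- function(network) {
  if (igraph::vcount(network) < 2L)
    stop_input("apl_net needs at least 2 nodes")
  apl_net_safe(network)
}

apl_net_safe <- function(network) {
  if (igraph::vcount(network) < 2L || igraph::ecount(network) == 0L)
    return(NA_real_)
  m <- suppressWarnings(igraph::mean_distance(network, unconnected = TRUE))
  if (!is.finite(m)) NA_real_ else m
}

#' Node clustering coefficient
#'
#' Fraction of possible triangles through the node:
#' `2 T(v) / (deg(v) (deg(v) - 1))`; nodes of degree < 2 score 0.
#'
#' @param network An igraph undirected network.
#' @param v A vertex name.
#' @return A real in `[0, 1]`.
#' @export
clustering_node <- function(network, v) {
  if (!v %in% igraph::V(network)$name) stop_input("unknown node: ", v)
  unname(igraph::transitivity(network, type = "local", vids = v,
                              isolates = "zero"))
}

#' Network average clustering coefficient
#'
#' Unweighted mean of the node clustering coefficient over all nodes.
#'
#' @param network An igraph undirected network (non-empty).
#' @return A real in `[0, 1]`.
#' @export
cc_net <- function(network) {
  if (igraph::vcount(network) == 0L) stop_input("empty network")
  cc_net_safe(network)
}

cc_net_safe <- function(network) {
  if (igraph::vcount(network) == 0L) return(NA_real_)
  mean(igraph::transitivity(network, type = "local", isolates = "zero"))
}

#' Per-node topology table
#'
#' Degree, average shortest-path length, closeness and clustering for
#' every node, computed from a single all-pairs BFS.
#'
#' @param network An igraph undirected network with named vertices.
#' @return A `data.frame` with columns `node`, `degree`, `apl_node`,
#'   `cc_node`, `clustering`, and the `is_hub` / `is_drug_target` flags
#'   when present.
#' @export
node_topology <- function(network) {
  if (igraph::vcount(network) == 0L) stop_input("empty network")
  d <- igraph::distances(network)
  reach <- is.finite(d)
  n_comp <- rowSums(reach)
  dsum <- rowSums(ifelse(reach, d, 0))
  out <- data.frame(
    node = igraph::V(network)$name,
    degree = unname(igraph::degree(network)),
    apl_node = ifelse(n_comp > 1L, dsum / n_comp, 0),
    cc_node = ifelse(n_comp > 1L, (n_comp - 1) / dsum, 0),
    clustering = unname(igraph::transitivity(network, type = "local",
                                             isolates = "zero")),
    stringsAsFactors = FALSE)
  for (attr in c("is_hub", "is_drug_target"))
    if (attr %in% igraph::vertex_attr_names(network))
      out[[attr]] <- igraph::vertex_attr(network, attr)
  rownames(out) <- NULL
  out
}

#' Network-level topology summary
#'
#' @param network An igraph undirected network.
#' @return List with `apl_net`, `cc_net`, `n_nodes`, `n_edges`,
#'   `n_components`, `lcc_size`. `apl_net`/`cc_net` are `NA` on degenerate
#'   (empty or edgeless) networks.
#' @export
network_topology <- function(network) {
  n <- igraph::vcount(network)
  comp <- if (n > 0L) igraph::components(network) else NULL
  list(apl_net = apl_net_safe(network),
       cc_net = cc_net_safe(network),
       n_nodes = n,
       n_edges = igraph::ecount(network),
       n_components = if (is.null(comp)) 0L else comp$no,
       lcc_size = if (is.null(comp)) 0L else max(comp$csize))
}
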