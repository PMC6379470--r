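# Drug attack and network-robustness assessment: remove the drug-target
# nodes, form the after/before quotients of the network indicators, and
# compare them with a null ensemble of uniform random graphs carrying the
# same node labels and edge count under the same attack.

#' Attack a network by removing drug-target nodes
#'
#' Removes `targets` (intersected with the node set) and all incident
#' edges, then reports network topology before and after together with
#' the robustness indicators `ri_apl = apl_net(after) / apl_net(before)`
#' and `ri_cc = cc_net(after) / cc_net(before)`. A destabilizing attack
#' lengthens paths (`ri_apl > 1`) and dissolves clustering (`ri_cc < 1`).
#' Quotients are `NA` when either side is undefined (e.g. the attack
#' leaves no connected pair); this is a reported outcome, not an error.
#'
#' @param network An igraph undirected network with named vertices.
#' @param targets Character vector of node names to remove.
#' @return List with `removed`, `before`, `after`, `ri_apl`, `ri_cc`,
#'   `pct_change_apl`, `pct_change_cc` (quotient minus 1, in percent).
#' @export
attack <- function(network, targets) {
  if (igraph::vcount(network) == 0L) stop_input("empty network")
  removed <- sort(intersect(igraph::V(network)$name, targets))
  before <- network_topology(network)
  after_g <- igraph::delete_vertices(network, removed)
  after <- network_topology(after_g)
  ri_apl <- quotient(after$apl_net, before$apl_net)
  ri_cc <- quotient(after$cc_net, before$cc_net)
  list(removed = removed, before = before, after = after,
       ri_apl = ri_apl, ri_cc = ri_cc,
       pct_change_apl = (ri_apl - 1) * 100,
       pct_change_cc = (ri_cc - 1) * 100)
}

# After/before ratio with an explicit no-change convention: a 0/0
# quotient (e.g. clustering of a triangle-free network before and after)
# reads as "unchanged", i.e. 1; only genuinely undefined sides yield NA.
quotient <- function(after, before) {
  if (is.na(after) || is.na(before)) return(NA_real_)
  if (before == 0) return(if (after == 0) 1 else NA_real_)
  after / before
}

#' Compare node topology of attacked vs other nodes
#'
#' Two-sided Welch t-tests on `apl_node` and `cc_node` between the
#' drug-attacked nodes and the remaining nodes. Attacked nodes sitting
#' closer to the rest of the network (shorter paths, larger closeness)
#' occupy more influential positions.
#'
#' @param network An igraph undirected network.
#' @param targets Character vector of drug-target node names.
#' @return List with `p_apl`, `p_cc`, `n_attacked`, `n_other` and per-group
#'   means (`mean_apl_attacked`, `mean_apl_other`, `mean_cc_attacked`,
#'   `mean_cc_other`).
#' @export
compare_attacked_nodes <- function(network, targets) {
  topo <- node_topology(network)
  att <- topo$node %in% targets
  if (sum(att) < 2L || sum(!att) < 2L)
    stop_input("insufficient group size: need >= 2 attacked and >= 2 other nodes")
  p_apl <- welch_p(topo$apl_node[att], topo$apl_node[!att])
  p_cc <- welch_p(topo$cc_node[att], topo$cc_node[!att])
  list(p_apl = p_apl, p_cc = p_cc,
       n_attacked = sum(att), n_other = sum(!att),
       mean_apl_attacked = mean(topo$apl_node[att]),
       mean_apl_other = mean(topo$apl_node[!att]),
       mean_cc_attacked = mean(topo$cc_node[att]),
       mean_cc_other = mean(topo$cc_node[!att]))
}

#' Generate the random-network null distribution of robustness indicators
#'
#' Each replicate draws a uniform random graph (G(n, m)) on the same
#' labeled node set with the same edge count as the observed network,
#' applies the same attack (removal of the same node labels) and records
#' both quotients. Replicates whose quotient is undefined (fragmentation
#' leaves no connected pair) are recorded as `NA` and excluded from
#' p-value denominators downstream, with the count reported.
#'
#' @param network The observed igraph network.
#' @param targets Character vector of attacked node names.
#' @param n_replicates Number of random networks (the customary ensemble
#'   size is 1000).
#' @param seed Integer seed; the ensemble is a pure function of it.
#' @return List with components `ri_apl` and `ri_cc`, each a list with
#'   `indicator`, `values`, `n_replicates`, `n_undefined`, `seed`.
#' @export
generate_null <- function(network, targets, n_replicates = 1000, seed) {
  if (igraph::vcount(network) == 0L) stop_input("empty network")
  if (n_replicates < 1L) stop_input("n_replicates must be >= 1")
  labels <- igraph::V(network)$name
  n <- length(labels)
  m <- igraph::ecount(network)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      g <- igraph::sample_gnm(n, m)
      g <- igraph::set_vertex_attr(g, "name", value = labels)
      res <- attack(g, targets)
      c(res$ri_apl, res$ri_cc)
    }, numeric(2))
  })
  mk <- function(ind, v) list(indicator = ind, values = unname(v),
                              n_replicates = n_replicates,
                              n_undefined = sum(is.na(v)), seed = seed)
  list(ri_apl = mk("ri_apl", vals[1L, ]), ri_cc = mk("ri_cc", vals[2L, ]))
}

#' Permutation p-value of an observed indicator against its null
#'
#' Uses the add-one estimator `p = (1 + b) / (1 + N)` where `b` counts
#' null values at least as extreme as the observed one in the stated
#' direction (`two_sided` doubles the smaller tail, capped at 1), so p is
#' never exactly zero: an observation exceeding all 1000 replicates
#' yields p < 0.001. Also flags whether the observation falls outside the
#' empirical 95% band (below the 2.5th or above the 97.5th percentile).
#'
#' @param observed Observed indicator value (finite).
#' @param null A null-distribution component from [generate_null()].
#' @param direction `"greater"`, `"less"` or `"two_sided"`.
#' @return List with `p`, `outside_95ci`, `n_used`, `n_undefined`.
#' @export
permutation_p <- function(observed, null,
                          direction = c("greater", "less", "two_sided")) {
  direction <- match.arg(direction)
  if (is.na(observed)) stop_input("observed indicator is undefined")
  vals <- null$values[!is.na(null$values)]
  if (!length(vals)) stop_input("null distribution has no defined values")
  n <- length(vals)
  p_greater <- (1 + sum(vals >= observed)) / (1 + n)
  p_less <- (1 + sum(vals <= observed)) / (1 + n)
  p <- switch(direction,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(p = p, outside_95ci = observed < ci[1L] || observed > ci[2L],
       n_used = n, n_undefined = length(null$values) - n)
}

#' Assess robustness of one compartment network under drug attack
#'
#' Convenience composition: attack, node-level comparison (when group
#' sizes allow), null ensemble, and one-sided destabilizing permutation
#' p-values (`ri_apl` upper tail, `ri_cc` lower tail) with outside-95%-CI
#' flags.
#'
#' @inheritParams generate_null
#' @return List with `attack`, `node_comparison` (or `NULL`), `null`
#'   summaries and `p_apl`/`p_cc` permutation results.
#' @export
assess_robustness <- function(network, targets, n_replicates = 1000, seed) {
  att <- attack(network, targets)
  node_cmp <- tryCatch(compare_attacked_nodes(network, targets),
                       error = function(e) NULL)
  null <- generate_null(network, targets, n_replicates, seed)
  p_apl <- if (!is.na(att$ri_apl))
    permutation_p(att$ri_apl, null$ri_apl, "greater") else NULL
  p_cc <- if (!is.na(att$ri_cc))
    permutation_p(att$ri_cc, null$ri_cc, "less") else NULL
  list(attack = att, node_comparison = node_cmp,
       null = null, p_apl = p_apl, p_cc = p_cc,
       n_replicates = n_replicates, seed = seed)
}

#' Position a drug across compartments
#'
#' The verdict is the unique compartment whose attack is significant for
#' both indicators in the destabilizing direction — observed `ri_apl`
#' above the null's 97.5th percentile and observed `ri_cc` below its
#' 2.5th percentile — while no other compartment qualifies; otherwise
#' `"inconclusive"`.
#'
#' @param assessments Named list (one element per compartment) of results
#'   from [assess_robustness()].
#' @return A positioning report list: per-compartment indicator values,
#'   node-level and permutation p-values, CI flags, and `verdict`.
#' @export
position_drug <- function(assessments) {
  if (length(assessments) < 2L)
    stop_input("positioning needs at least 2 compartments")
  if (is.null(names(assessments)) || any(!nzchar(names(assessments))))
    stop_input("assessments must be named by compartment")
  comp <- lapply(assessments, function(a) {
    destab_apl <- !is.null(a$p_apl) && a$p_apl$outside_95ci &&
      a$attack$ri_apl > 1
    destab_cc <- !is.null(a$p_cc) && a$p_cc$outside_95ci &&
      a$attack$ri_cc < 1
    list(
      n_nodes = a$attack$before$n_nodes,
      n_edges = a$attack$before$n_edges,
      n_attacked = length(a$attack$removed),
      ri_apl = a$attack$ri_apl,
      ri_cc = a$attack$ri_cc,
      pct_change_apl = a$attack$pct_change_apl,
      pct_change_cc = a$attack$pct_change_cc,
      node_p_apl = if (is.null(a$node_comparison)) NA_real_ else a$node_comparison$p_apl,
      node_p_cc = if (is.null(a$node_comparison)) NA_real_ else a$node_comparison$p_cc,
      perm_p_apl = if (is.null(a$p_apl)) NA_real_ else a$p_apl$p,
      perm_p_cc = if (is.null(a$p_cc)) NA_real_ else a$p_cc$p,
      outside_95ci_apl = !is.null(a$p_apl) && a$p_apl$outside_95ci,
      outside_95ci_cc = !is.null(a$p_cc) && a$p_cc$outside_95ci,
      n_undefined_null_apl = a$null$ri_apl$n_undefined,
      n_undefined_null_cc = a$null$ri_cc$n_undefined,
      destabilized = destab_apl && destab_cc,
      n_null = a$n_replicates,
      seed = a$seed)
  })
  hits <- names(comp)[vapply(comp, `[[`, logical(1), "destabilized")]
  list(compartments = comp,
       verdict = if (length(hits) == 1L) hits else "inconclusive")
}
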