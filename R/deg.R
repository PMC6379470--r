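# Differential-expression stage: per-gene two-sample test and the
# fold-change / p-value filter that defines each compartment's DEG list.

#' Test one gene for differential expression
#'
#' Fold change is the linear-scale ratio of group means (case / control).
#' The default test is Welch's unequal-variance t on log-transformed
#' values, the standard choice for microarray intensities; a linear-scale
#' Welch t is available for data already on an additive scale.
#'
#' @param case_values,control_values Numeric vectors of linear-scale
#'   expression, length >= 2 each.
#' @param test `"welch_log"` (default) or `"welch_linear"`.
#' @return List with elements `fold_change` and `p_value`.
#' @export
test_gene <- function(case_values, control_values,
                      test = c("welch_log", "welch_linear")) {
  test <- match.arg(test)
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop_input("need at least 2 values per group")
  if (any(case_values < 0) || any(control_values < 0))
    stop_input("expression values must be non-negative")
  m_ctrl <- mean(control_values)
  if (m_ctrl == 0) stop_input("undefined fold change: control mean is 0")
  fc <- mean(case_values) / m_ctrl
  if (test == "welch_log") {
    if (any(case_values <= 0) || any(control_values <= 0))
      stop_input("log-scale test requires strictly positive values; use test = 'welch_linear'")
    x <- log(case_values); y <- log(control_values)
  } else {
    x <- case_values; y <- control_values
  }
  p <- welch_p(x, y)
  list(fold_change = fc, p_value = p)
}

# Welch t p-value robust to zero-variance groups (t.test() refuses
# essentially-constant data): equal constant groups are maximally
# non-significant, different constant groups maximally significant.
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Call differentially expressed genes
#'
#' A gene is called up when fold change >= `fc_up` and p < `p_max`, down
#' when fold change <= `fc_down` and p < `p_max`, and `none` otherwise.
#' Note the asymmetric defaults (1.1 up, 0.91 down) and the inclusive
#' fold-change boundaries, with raw (uncorrected) p-values.
#'
#' @param mat An [expression_matrix()].
#' @param fc_up Up-regulation fold-change threshold (inclusive), > 1.
#' @param fc_down Down-regulation threshold (inclusive), < 1.
#' @param p_max Significance threshold on the raw p-value (exclusive).
#' @inheritParams test_gene
#' @return A `data.frame` with columns `gene`, `fold_change`, `p_value`,
#'   `direction` (one row per gene).
#' @export
call_degs <- function(mat, fc_up = 1.1, fc_down = 0.91, p_max = 0.05,
                      test = c("welch_log", "welch_linear")) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!(fc_down < 1 && 1 < fc_up))
    stop_input("need fc_down < 1 < fc_up")
  test <- match.arg(test)
  case_cols <- mat$group_labels == "case"
  res <- apply(mat$values, 1L, function(v)
    unlist(test_gene(v[case_cols], v[!case_cols], test = test)))
  fc <- res["fold_change", ]
  p <- res["p_value", ]
  direction <- rep("none", length(fc))
  direction[fc >= fc_up & p < p_max] <- "up"
  direction[fc <= fc_down & p < p_max] <- "down"
  data.frame(gene = mat$gene_ids, fold_change = unname(fc),
             p_value = unname(p), direction = direction,
             stringsAsFactors = FALSE)
}

#' Extract the called DEG symbols from a DEG table
#' @param degs A `data.frame` from [call_degs()].
#' @return Character vector of genes with direction != "none".
#' @export
deg_genes <- function(degs) sort(degs$gene[degs$direction != "none"])

#' Compare DEG lists from two compartments
#'
#' Partitions the union of called DEGs into compartment-private and shared
#' sets (the Venn structure of a two-compartment comparison).
#'
#' @param degs_a,degs_b DEG tables from [call_degs()].
#' @return List with gene sets `only_a`, `only_b`, `shared`.
#' @export
compare_compartment_degs <- function(degs_a, degs_b) {
  a <- deg_genes(degs_a); b <- deg_genes(degs_b)
  list(only_a = setdiff(a, b), only_b = setdiff(b, a),
       shared = intersect(a, b))
}

#' Write a DEG table as TSV
#' @param degs A `data.frame` from [call_degs()].
#' @param path Output path.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
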