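# Readers and writers for every external format the pipeline touches:
# expression TSVs, STRING-style interaction tables, drug-target tables,
# plain gene lists, GMT term sets, network exports and the JSON report.

#' Construct an expression matrix object
#'
#' A genes-by-samples matrix of linear-scale, non-negative expression values
#' with a case/control label per sample.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Dimnames
#'   must carry gene symbols and sample ids.
#' @param group_labels Character vector, one of `"case"`/`"control"` per
#'   sample, in column order.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, group_labels) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("expression values must carry gene and sample dimnames")
  if (nrow(values) == 0L) stop_input("no genes in expression matrix")
  genes <- norm_symbols(rownames(values))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_input("duplicate gene id(s): ", paste(dup, collapse = ", "))
  rownames(values) <- genes
  if (length(group_labels) != ncol(values))
    stop_input("one group label per sample required")
  if (!all(group_labels %in% c("case", "control")))
    stop_input("group labels must be 'case' or 'control'")
  if (!all(c("case", "control") %in% group_labels))
    stop_input("both case and control groups must be non-empty")
  if (any(!is.finite(values)) || any(values < 0))
    stop_input("expression values must be finite and non-negative")
  structure(
    list(values = values,
         gene_ids = genes,
         sample_ids = colnames(values),
         group_labels = stats::setNames(group_labels, colnames(values))),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group_labels == "case"), sum(x$group_labels == "control")))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene symbols in the first column.
#'
#' @param path Path to a TSV file.
#' @param group_map Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_map) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop_input("no genes in ", path)
  genes <- norm_symbols(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  missing <- setdiff(colnames(vals), names(group_map))
  if (length(missing))
    stop_input("sample(s) missing from group_map: ", paste(missing, collapse = ", "))
  expression_matrix(vals, unname(group_map[colnames(vals)]))
}

#' Write an expression matrix to TSV
#' @param mat An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = mat$gene_ids, mat$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and clean a gene-gene interaction table
#'
#' STRING-style confidence-scored undirected interactions. Self-pairs are
#' dropped; duplicate unordered pairs are collapsed keeping the maximum
#' confidence; `score_scale = "thousand"` divides combined scores on the
#' 0-1000 integer scale by 1000 so that downstream thresholds (the usual
#' 0.4 medium-confidence cut) always refer to the unit scale.
#'
#' @param path Path to a TSV with columns `gene_a`, `gene_b`, `score`.
#' @param score_scale `"unit"` (scores already in `[0,1]`) or `"thousand"`.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `confidence`.
#' @export
read_interaction_table <- function(path, score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop_input("interaction table needs gene_a, gene_b, score columns")
  interaction_table(tab[[1L]], tab[[2L]], tab[[3L]], score_scale = score_scale)
}

#' Build a cleaned interaction table from vectors
#'
#' @param gene_a,gene_b Character vectors of interaction endpoints.
#' @param score Numeric scores on the scale named by `score_scale`.
#' @inheritParams read_interaction_table
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `confidence`,
#'   one row per unordered pair, endpoints sorted within row.
#' @export
interaction_table <- function(gene_a, gene_b, score,
                              score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  a <- norm_symbols(gene_a); b <- norm_symbols(gene_b)
  score <- as.numeric(score)
  hi <- if (score_scale == "thousand") 1000 else 1
  if (any(!is.finite(score)) || any(score < 0) || any(score > hi))
    stop_input("interaction score outside declared ", score_scale,
               " scale [0, ", hi, "]")
  conf <- if (score_scale == "thousand") score / 1000 else score
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  conf <- conf[keep]
  if (length(a2) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  key <- paste(a2, b2, sep = "\r")
  conf <- tapply(conf, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                    gene_b = vapply(parts, `[[`, "", 2L),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a drug-target table and keep high-possibility targets
#'
#' Returns the union of target genes whose possibility score is strictly
#' greater than `min_score` (the customary cut for BATMAN-TCM-style
#' predictions is 20).
#'
#' @param path TSV with columns compound, gene, score.
#' @param min_score Keep genes with score strictly greater than this.
#' @return Character vector of gene symbols (a gene set).
#' @export
read_drug_targets <- function(path, min_score = 20) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(character())
  if (ncol(tab) < 3L) stop_input("drug-target table needs compound, gene, score columns")
  score <- as.numeric(tab[[3L]])
  if (any(!is.finite(score)) || any(score < 0))
    stop_input("negative or non-numeric possibility score in ", path)
  sort(unique(norm_symbols(tab[[2L]][score > min_score])))
}

#' Read a plain gene list (one symbol per line, '#' comments allowed)
#' @param path Path to the list file.
#' @return Character vector of unique, upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  sort(unique(norm_symbols(lines[nzchar(lines)])))
}

#' Write a gene list, one symbol per line
#' @param genes Character vector of symbols.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(norm_symbols(genes))), path)
  invisible(path)
}

#' Read GMT-format term sets
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term -> gene set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) sort(unique(norm_symbols(p[-(1:2)]))))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Export a disease network
#'
#' `"graphml"` preserves node attributes (hub and drug-target flags);
#' `"edgelist"` writes a plain two-column TSV of symbol pairs.
#'
#' @param network An igraph disease network.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml")) {
  if (!format[1L] %in% c("edgelist", "graphml"))
    stop_input("unknown network format: ", format[1L])
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(el)) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path Path to the file.
#' @inheritParams write_network
#' @return An igraph object.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # graphml round-trips logical attributes as numeric; restore them
    for (attr in c("is_hub", "is_drug_target"))
      if (attr %in% igraph::vertex_attr_names(g))
        g <- igraph::set_vertex_attr(g, attr,
                                     value = as.logical(igraph::vertex_attr(g, attr)))
    g
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(igraph::make_empty_graph(0, directed = FALSE))
    el <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    igraph::graph_from_edgelist(el, directed = FALSE)
  }
}

#' Write a positioning report as JSON
#'
#' The serialization is deterministic: identical report objects produce
#' byte-identical files, so a fixed-seed run is fully reproducible.
#'
#' @param report A positioning report (see [position_drug()]) or any
#'   JSON-serializable list.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path Path to the JSON file.
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
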