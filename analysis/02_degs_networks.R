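#!/usr/bin/env Rscript
# Stage 2: call DEGs per compartment and assemble the disease networks.
#
# The filter is p < 0.05 with fold change >= 1.1 (up) or <= 0.91 (down);
# networks keep DEG-DEG interactions with confidence > 0.4 and flag hubs
# (degree > 2 x median) and drug-attacked nodes. Reads the files written
# by analysis/01_simulate.R.

suppressPackageStartupMessages(library(netrobust))

in_dir <- "results/inputs"
out_dir <- "results"
stopifnot(dir.exists(in_dir))

targets <- read_gene_list(file.path(in_dir, "drug_targets.txt"))

for (k in c("A", "B")) {
  expr <- read_expression_matrix(
    file.path(in_dir, sprintf("expression_%s.tsv", k)),
    group_map = local({
      samples <- strsplit(readLines(file.path(in_dir, sprintf("expression_%s.tsv", k)),
                                    n = 1), "\t")[[1]][-1]
      stats::setNames(ifelse(grepl("case", samples), "case", "control"),
                      samples)
    }))
  ints <- read_interaction_table(
    file.path(in_dir, sprintf("interactions_%s.tsv", k)), "unit")

  degs <- call_degs(expr)
  write_deg_table(degs, file.path(out_dir, sprintf("degs_%s.tsv", k)))
  truth <- c(read_gene_list(file.path(in_dir, sprintf("truth_up_%s.txt", k))),
             read_gene_list(file.path(in_dir, sprintf("truth_down_%s.txt", k))))
  called <- deg_genes(degs)
  cat(sprintf("compartment %s: %d DEGs called (%d planted, sensitivity %.2f)\n",
              k, length(called), length(truth),
              length(intersect(called, truth)) / length(truth)))

  net <- flag_hubs(build_network(degs, ints, min_confidence = 0.4))
  flagged <- flag_drug_targets(net, targets)
  cat(sprintf("  network: %d nodes, %d edges, %d hubs, %d drug-attacked nodes\n",
              igraph::vcount(net), igraph::ecount(net),
              length(hub_genes(net)), length(flagged$attacked)))
  write_network(flagged$network,
                file.path(out_dir, sprintf("network_%s.graphml", k)),
                format = "graphml")
  utils::write.table(node_topology(flagged$network),
                     file.path(out_dir, sprintf("topology_%s.tsv", k)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("DEG tables, networks and topology tables written under results/\n")
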