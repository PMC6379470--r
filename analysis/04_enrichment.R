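#!/usr/bin/env Rscript
# Stage 4: enrichment statistics on the called DEG sets.
#
# Demonstrates the two generic statistics on the synthetic study: a 2x2
# chi-square comparing how the drug's targets distribute over the two
# compartments' DEG lists, and hypergeometric enrichment of the
# compartment-A DEGs in synthetic term sets built around the planted
# truth (a positive control) and random gene sets (negative controls).

suppressPackageStartupMessages(library(netrobust))

targets <- read_gene_list("results/inputs/drug_targets.txt")
degs_a <- utils::read.delim("results/degs_A.tsv")
degs_b <- utils::read.delim("results/degs_B.tsv")
called_a <- deg_genes(degs_a)
called_b <- deg_genes(degs_b)
universe <- sort(degs_a$gene)

tab <- matrix(c(sum(called_a %in% targets), sum(!called_a %in% targets),
                sum(called_b %in% targets), sum(!called_b %in% targets)),
              2, byrow = TRUE,
              dimnames = list(c("degs_A", "degs_B"),
                              c("targeted", "untargeted")))
print(tab)
chi <- chi_square_2x2(tab)
cat(sprintf("chi-square = %.3f, p = %.3g\n", chi$chi2, chi$p))

truth_a <- c(read_gene_list("results/inputs/truth_up_A.txt"),
             read_gene_list("results/inputs/truth_down_A.txt"))
set.seed(20260926)
terms <- c(list(planted_A = truth_a),
           stats::setNames(lapply(1:5, function(i) sample(universe, 50)),
                           paste0("random_", 1:5)))
enr <- hypergeom_enrich(called_a, terms, universe)
print(enr)
utils::write.table(enr, "results/enrichment_A.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Enrichment table written to results/enrichment_A.tsv\n")
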