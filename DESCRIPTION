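Package: netrobust
Title: Drug Positioning by Robustness Analysis of Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Positions a multi-target drug to the disease compartment whose
    molecular network it destabilizes most. Builds per-compartment disease
    networks from differentially expressed genes and confidence-filtered
    protein-protein interactions, simulates drug attack by removing target
    nodes, quantifies the robustness change with average shortest path length
    and clustering coefficient quotients, and assesses significance against a
    null ensemble of uniform random graphs with preserved node and edge
    counts. Includes a synthetic data generator for expression matrices,
    scale-free interaction networks and hub-biased drug-target sets, plus
    generic chi-square and hypergeometric enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
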