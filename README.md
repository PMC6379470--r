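# netrobust

Positioning a multi-target drug to the disease compartment whose
molecular network it destabilizes most.

## The problem

Diseases such as hypertensive nephropathy damage distinct tissue
compartments (renal glomeruli vs the tubulointerstitium) through
distinct molecular programs, and a multi-component drug rarely acts on
both equally. Given per-compartment case/control expression data, a
confidence-scored gene–gene interaction table and the drug's predicted
target genes, `netrobust` asks: *which compartment's disease network
does the drug attack harder?*

## The method

1. **Differential expression.** Per gene, fold change is the
   linear-scale ratio of case/control means; Welch's t on log values
   supplies the p-value. A gene is a DEG when p < 0.05 and FC ≥ 1.1
   (up) or FC ≤ 0.91 (down).
2. **Disease network.** The DEG-induced subgraph of the interaction
   table, keeping edges with confidence > 0.4. Hubs are nodes with
   degree > 2 × median degree; the drug's targets present in the
   network are the *attacked* nodes.
3. **Node topology.** For a source node *s* in a component of size *n*:
   APL_node(s) = Σ_t d(s,t)/n and CC_node(s) = (n−1)/Σ_t d(s,t);
   clustering C_v = 2T(v)/(deg(v)(deg(v)−1)). Attacked vs other nodes
   are compared with unpaired Welch t-tests.
4. **Drug attack and robustness.** Removing the attacked nodes yields
   the robustness indicators RI = after/before quotients of
   APL_net (mean distance over connected ordered pairs) and
   CC_net (mean node clustering). Destabilization = longer paths
   (RI_APL > 1) and dissolved clustering (RI_CC < 1).
5. **Permutation null.** 1000 uniform random graphs with the same node
   labels and edge count undergo the same attack; the observed
   quotients get add-one permutation p-values, p = (1+b)/(1+N), and an
   outside-95%-CI flag.
6. **Verdict.** The drug is positioned to the unique compartment
   significant for both indicators in the destabilizing direction.

A synthetic-data module generates the whole study — planted DE genes,
scale-free interaction networks, hub-biased target sets — so every
stage is testable without downloads, and generic chi-square (2×2) and
hypergeometric enrichment statistics are included.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated two-compartment study in which the drug's targets are drawn
hub-biased (degree exponent 3) from compartment A's network and
uniformly from B's:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_degs_networks.R
Rscript analysis/03_robustness_positioning.R
Rscript analysis/04_enrichment.R
```

Output of the positioning stage (seed 20260926):

```
compartment A: ri_apl = 1.409 (perm p = 0.000999), ri_cc = 0.103 (perm p = 0.000999)
  attacked vs other nodes: p_apl = 7.61e-07, p_cc = 6.2e-06 (17 vs 83 nodes)
compartment B: ri_apl = 0.982 (perm p = 1), ri_cc = 1.026 (perm p = 0.6094)
  attacked vs other nodes: p_apl = 0.426, p_cc = 0.357 (20 vs 84 nodes)
verdict: A
```

Reading: attacking A's network lengthens its average shortest path by
41% and collapses its clustering to 10% of the pre-attack value, both
beyond all 1000 random-network replicates (p = 1/1001 < 0.001), while
B's network barely moves — so the drug is positioned to compartment A,
which is exactly where its hub-directed targets were planted. The
node-level t-tests agree: A's attacked nodes occupy significantly more
central positions.

Programmatic use:

```r
library(netrobust)
study <- simulate_study(synthetic_config(seed = 1))
report <- run_pipeline(pipeline_config(
  compartments = list(
    A = list(expression = study$expression$A$matrix,
             interactions = study$interactions$A),
    B = list(expression = study$expression$B$matrix,
             interactions = study$interactions$B)),
  targets = study$targets, n_null = 1000, seed = 1))
report$verdict
```

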