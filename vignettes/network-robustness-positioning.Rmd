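---
title: "Positioning multi-target drugs by disease-network robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning multi-target drugs by disease-network robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrobust)
```

## The model

A compartment's disease state is summarized as an undirected, unweighted
*disease network*: nodes are the genes differentially expressed between
patients and controls in that compartment, edges are curated gene–gene
interactions passing a confidence threshold. A multi-target drug is
modelled as a simultaneous *attack*: all of its target nodes present in
the network are removed at once, together with their incident edges.
The working assumption is that a drug matters most where it dismantles
the disease network's communication structure; no kinetics, dosage or
directionality of regulation enter the model.

Two indicators quantify the damage, each an after/before quotient
(robustness indicator, RI):

* **RI_APL** — quotient of the network average shortest-path length,
  `APL_net = Σ d(s,t) / n(n−1)` over ordered pairs. Paths lengthening
  (RI_APL > 1) means the attack removed shortcuts the network depended
  on.
* **RI_CC** — quotient of the mean node clustering coefficient,
  `C_v = 2T(v) / (deg(v)(deg(v)−1))`. Clustering collapsing (RI_CC < 1)
  means local neighbourhoods dissolved.

Node-level importance of the attacked set is assessed separately:
`APL_node(s) = Σ_t d(s,t)/n` and closeness
`CC_node(s) = (n−1)/Σ_t d(s,t)` are compared between attacked and
non-attacked nodes with two-sided unpaired Welch t-tests. Central
attacked nodes (short paths, high closeness) predict a damaging attack.

## Significance: the random-network null

An RI quotient has no analytic reference distribution, so significance
comes from an ensemble of random networks: each replicate is a uniform
random graph G(n, m) on the *same labelled node set* with the *same
edge count*, subjected to the *same* attack (removal of the same node
labels). With 1000 replicates, the observed quotient gets

* a one-sided add-one permutation p-value `p = (1 + b) / (1 + N)`,
  where `b` counts replicates at least as extreme in the destabilizing
  direction (upper tail for RI_APL, lower for RI_CC) — never exactly
  zero, so an observation beyond all 1000 replicates reports
  p = 1/1001 < 0.001;
* an outside-95%-band flag (below the 2.5th or above the 97.5th
  empirical percentile).

The *verdict* assigns the drug to the unique compartment that is
outside the band for **both** indicators in the destabilizing direction
while no other compartment qualifies; anything else is "inconclusive".

Two design points were genuinely open and are decided as follows.
First, the null preserves node and edge counts only, not the degree
sequence: a degree-preserving rewiring null would by construction
remove the very hub structure whose vulnerability is being tested.
Second, "the same attack" on a replicate means removing the same node
*labels*; in the uniform model labels are exchangeable, so this equals
removing an equally sized random-role node set, and it keeps the
attacked set well defined on every replicate.

## Conventions on disconnected graphs

Attack can fragment a network, and the textbook formulas assume
connectivity. All distance sums are therefore restricted to the source
node's connected component, with the component size standing in for
`n`; `APL_net` averages over connected ordered pairs only; isolated
nodes score 0 for `APL_node` and `CC_node`. A network left with no
connected pair has undefined (`NA`) indicators — reported, not
imputed; null replicates with undefined quotients are excluded from
the p-value denominator with their count logged. A 0/0 quotient (e.g.
clustering of a triangle-free network before and after) reads as
"unchanged", i.e. 1, so the empty attack is exactly the identity. The
component count and largest-component size are always carried in the
report so fragmentation stays visible. `APL_node` divides by the full
component size `n` (including the zero self-distance), following the
indicator's printed form rather than the `n−1` convention.

## Thresholds and parameters

| parameter | default | meaning |
|---|---|---|
| `fc_up` / `fc_down` | 1.1 / 0.91 | linear fold-change cut-offs, inclusive; deliberately asymmetric (0.91, not 1/1.1) |
| `p_max` | 0.05 | raw per-gene p cut-off (exclusive); no multiple-testing correction |
| `min_confidence` | 0.4 | interaction confidence, strict `>`; 0–1000 scores are divided by 1000 first |
| `hub_factor` | 2 | hub iff degree > factor × median degree (midpoint median on even counts) |
| `target_min_score` | 20 | possibility-score cut for drug targets, strict `>` |
| `n_null` | 1000 | null-ensemble size |

The per-gene test defaults to Welch's t on natural-log values — the
standard microarray noise model — and is pluggable
(`test = "welch_linear"`); fold changes are always linear-scale mean
ratios. Gene symbols are upper-cased at ingest because expression,
interaction, target and disease-gene sources are matched by symbol.
All thresholds written as "larger than" are strict inequalities; the
fold-change bounds written with ≥/≤ are inclusive, and the boundary
tests pin both behaviours.

## What the synthetic generator emulates

`simulate_study()` produces a two-compartment study shaped like a
kidney-biopsy microarray cohort: 15 cases vs 27 controls, log-normal
expression (gene-level log-means ~ N(log 100, 1), noise sd 0.3 on the
log scale), 5% of 2000 genes planted as DE at fold 1.5 (split evenly
up/down, 30% of the planted set shared between compartments);
per-compartment scale-free interaction networks (preferential
attachment, 150 nodes, 6 edges per node) whose node sets cover the
planted DE genes, with 25% of edge confidences below the 0.4 cut so
the filter is exercised; and a drug-target set drawn with selection
weight `degree^hub_bias` — hub-directed (exponent 3) in compartment A,
indifferent (exponent 0) in B. The interaction density is calibrated
so the DEG-induced disease network reaches a mean degree near 7,
typical of curated interactions among co-regulated genes; much sparser
networks fragment under attack, which shortens the surviving paths and
masks destabilization (a behaviour the indicators correctly report,
but a different regime from the one of interest).

What the generator does **not** emulate: probe-level microarray
effects, batch effects, correlated expression between interacting
genes, the semantics of real interaction confidence scores, or
compound-level target structure. Passing tests therefore demonstrate
that the *method* recovers planted signals under its own statistical
assumptions, not that any particular real drug positioning is correct.

## Validation experiments and problem sizes

Three seeded experiments, all runnable via the exported
`*_experiment()` functions and recomputed by `scripts/acceptance.R`:

* **Null calibration** — 200 observed networks drawn from the null
  itself (60 nodes, 150 edges, 10 random targets, 200-replicate
  nulls): the fraction of seeds with p < 0.05 should sit near 0.05.
* **Planted-attack recovery** — 50 paired studies of matched
  preferential-attachment networks (250 nodes, ~750 edges, 20 targets,
  500-replicate nulls), hub bias 3 vs 0: the hub-attacked
  compartment's destabilizing p should be the smaller one in ≥80% of
  seeds and outside the 95% band in most.
* **DEG recovery** — 20 matrices at 15 vs 27 samples, fold 1.5, noise
  0.3: sensitivity ≥ 0.8 with ≤ 5% wrong-direction calls among planted
  genes.

Metric correctness is pinned by brute-force oracles (handwritten BFS
and exhaustive triangle enumeration) on 100 random graphs of up to 30
nodes at 1e-12, plus closed forms (complete graphs, paths with
`APL = (n+1)/3`, triangle-free trees). These sizes keep the full suite
within minutes on one core while leaving the statistical checks
well-powered; they are the package's chosen validation scale, not a
limit of the method.

## Numerical and degenerate-input choices

Zero-variance gene vectors would break `t.test()`; the package's Welch
wrapper returns p = 1 for identical constant groups and p = 0 for
different constant groups. Fold change is undefined when the control
mean is 0 (hard error). Interaction cleaning collapses duplicate
unordered pairs to the maximum confidence (conservative retention
before thresholding) and is idempotent. Isolated DEGs are excluded
from the network by default — real disease-network node counts imply
only interacting DEGs enter — but `keep_isolated = TRUE` retains them.
Every stochastic stage draws its seed deterministically from one
top-level seed via a fixed integer hash, so an entire run, including
the JSON report bytes, is a pure function of config and seed.

## Known limitations

* The per-gene test is a stand-in for richer microarray statistics
  (moderated t, SAM-style permutation d); only the fold-change +
  p-value filter is fixed by the method.
* The uniform G(n, m) null ignores degree structure by design; a
  compartment can also be flagged simply because its network is small
  enough to fragment, which the `n_components`/`lcc_size` fields make
  visible but the verdict rule does not model.
* Edge confidences are used only as a filter; all metrics are
  unweighted.
* With more than two compartments the verdict requires uniqueness; no
  ranking beyond the p-values is attempted.
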