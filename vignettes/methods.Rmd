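---
title: "Effect radius and pathway crosstalk of drug combinations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect radius and pathway crosstalk of drug combinations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugcombnet)
```

## The question

Effective drug combinations pair compounds whose targets sit close together
in the cell's functional wiring. `drugcombnet` quantifies this with two
network statistics computed over a genetic interaction network (genes as
nodes, functional gene–gene relationships as undirected edges) and a
collection of pathway gene sets:

* the **effect radius** of a combination, and
* the composition of the **pathway pairs** its component drugs target.

Both are compared against a degree-preserving random-combination null.

## The model

**Drug–drug distance.** For drugs $i$ and $j$ with target sets $T_i$ and
$T_j$,

$$\mathrm{dis}(i,j) \;=\; \min_{t_i \in T_i,\; t_j \in T_j} d(t_i, t_j),$$

where $d$ is the unweighted shortest-path hop distance in the genetic
interaction network. A shared target gives distance 0; the distance is
unavailable when every target pair spans distinct components (or a target is
absent from the network).

**Effect radius.** For a combination with member set $M$ and
$D = \{\{i,j\} \subset M\}$ the set of its unordered drug pairs,

$$R \;=\; \frac{1}{|D'|} \sum_{\{i,j\} \in D'} \mathrm{dis}(i,j),$$

where $D' \subseteq D$ is the subset of pairs whose distance is available.
Unavailable pairs are excluded from numerator and denominator rather than
imputed with a large constant — the statistic conditions on availability —
and their count is reported (`n_pairs_unreachable`) so the alternative
convention can be audited. $R$ is undefined when $D'$ is empty. For
two-drug combinations the ordered/unordered reading of $|D|$ is immaterial;
for larger combinations we use unordered pairs, each counted once.

**Pathway-pair categories.** Each drug is associated with every pathway
containing one of its targets. For each member pair, every pathway of one
drug is paired with every pathway of the other, and the pair is labelled:

| label | definition |
|---|---|
| IDENTICAL | same pathway identifier |
| CROSS_TALKING | gene sets share at least one gene |
| INTERACTING | an interaction edge joins the two gene sets |
| PARALLEL | none of the above |

A pair can satisfy several definitions (overlapping pathways often also have
bridging edges), so a precedence is needed; the source analysis does not
state one. We use IDENTICAL > CROSS_TALKING > INTERACTING > PARALLEL:
sharing a gene is the stronger, containment-like relation, so it wins, and
the four categories stay disjoint. A consequence worth noting is that
whether edges internal to the shared genes "count" for INTERACTING is moot —
such pairs are already CROSS_TALKING. Two distinct identifiers with equal
gene sets are CROSS_TALKING, not IDENTICAL. A combination's profile is the
category proportions over all its pathway pairs; combinations with a member
associated with no pathway get an empty profile and are excluded from
comparisons.

**The null model.** The drug cocktail network has drugs as nodes and an edge
for every pair of drugs co-occurring in a retained combination (multi-drug
combinations enter as cliques). Random combinations are the edges of
degree-preserving shuffles of this network: repeated double-edge swaps
(rewire $(a,b),(c,d)$ to $(a,d),(c,b)$) that reject any swap creating a
self-loop or multi-edge. The reference analysis describes only "shuffling
while preserving the degree"; we chose the double-edge-swap mechanism, with
an attempt budget of `n_swaps_per_edge` × |E| (default 10 per edge, which
empirically leaves fewer than half the original edges in place on sparse
graphs — see the mixing test). The sampler makes no claim of exactly uniform
sampling over the degree-constrained graph space, and connectedness is not
preserved. Replicate $r$ of an ensemble uses seed `master_seed + r`, so a
single integer reproduces the whole ensemble.

**Comparison.** Real and null samples (radii, or per-combination category
proportions) are compared with the Wilcoxon rank-sum test: exact enumeration
when the pooled sample has ≤ 12 observations without ties, otherwise the
normal approximation with midranks, tie correction and continuity
correction. Null values are pooled across all replicates into one sample by
default; whether the reference analysis pooled or summarized per replicate
is not determinable from its description, so a `replicate_mean` mode is also
provided and the mode used is recorded in every result. Sidedness likewise
is not stated there despite directional claims; the pipeline default is
two-sided (conservative), and the one-sided alternatives are available where
a direction is pre-specified. Raw p-values are reported without
multiple-testing correction, matching the reference analysis; a rank-biserial
effect size is printed for context.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 1e-7 | strict (<) retention threshold on interaction p-values |
| `n_null_replicates` | 1000 | degree-preserving shuffles in the null ensemble |
| `n_swaps_per_edge` | 10 | swap attempts per edge per shuffle |
| `radius_stratum_threshold` | 3 | strata boundary; R = 3 falls in the lower stratum (≤ 3) |
| `interacting_proportion_threshold` | 0.4 | strict (>) selection of interacting-pathway targeters |

The filters are deliberately strict on the stated side: an interaction with
p-value exactly at the threshold is dropped, and a combination whose
interacting proportion is exactly 0.4 is not selected. Duplicate interaction
rows collapse to the minimum p-value (conservative retention). Combinations
containing a drug without targets, without an ATC code, or absent from the
drug table are discarded — discarding, not erroring, mirrors the upstream
curation policy. Identifier matching is exact, case-sensitive string
equality; the package provides no gene/drug alias resolution, so inputs must
share one identifier namespace.

## The synthetic-data generator

Desk-scale reproduction of the original findings is impossible: they depend
on database snapshots (combination lists, drug annotations, the genetic
interaction map, the pathway collection) that are not printed anywhere.
`generate_bundle()` therefore creates complete input bundles with *planted*
structure so every pipeline property can be tested end to end:

* **Interaction graph** — Erdős–Rényi by default with
  `round(n_genes * interaction_density)` edges (default 300 genes, 600
  edges); a preferential-attachment option exists because real interaction
  networks are heavy-tailed. Kept edges get p-values strictly below the
  threshold; a configurable fraction of decoy rows above the threshold
  exercises the strict filter.
* **Pathways** — 30 sets of 6–12 genes by default, with genes recruited from
  earlier pathways with probability `pathway_overlap_prob` (0.1). These
  sizes keep random pathway pairs mostly PARALLEL, leaving headroom for a
  planted interacting signal; denser collections push the background
  proportion of CROSS_TALKING/INTERACTING pairs toward one and drown any
  signal, which is a property of the statistic, not of the generator.
* **Drugs and combinations** — 250 drugs with 1–4 targets; 100 true pairwise
  combinations drawn from disjoint annotated drugs; 5% of drugs lack ATC
  codes or targets, and a few decoy combinations touch them to exercise the
  annotation filter.
* **Planted signal** — with probability `planted_radius_bias` (0.8) a
  combination's partners receive targets within `d_plant` (1) hops; with
  probability `planted_crosstalk_bias` (0.8) the partners' targets are
  *replaced* by the two endpoints of an interaction edge bridging two
  disjoint pathways, which concentrates the combination's profile on
  edge-bridged pathway pairs. Replacement rather than addition is what makes
  the proportion (not merely the count) of INTERACTING pairs rise.

What the generator does **not** emulate: real degree distributions of
curated interaction maps, hierarchical/overlapping pathway structure (KEGG
pathways share far more genes than these sets), polypharmacology beyond a
handful of targets, and any correlation between combination type and
mechanism. Passing tests on these bundles demonstrate that the pipeline
recovers signal of the planted kind and stays calibrated in its absence —
they say nothing about effect sizes in real databases.

`worked_toy_bundle()` writes a 12-gene fixture whose every radius,
classification, proportion, stratum and tally was computed by hand and is
shipped as a manifest; it pins the boundary conventions (a radius of exactly
3, an interacting proportion of exactly 0.4, an undefined radius, a filtered
combination, a decoy interaction row).

## Numerical and degenerate-input choices

* Distances are computed by breadth-first search from each queried target
  gene and cached per source; the contract is the distance mapping, not the
  traversal order.
* A gene absent from the interaction network is unreachable from everything
  except itself (`dist(g, g) = 0` always).
* A degree sequence with a unique simple realization (e.g. a star) cannot be
  shuffled; the input is returned with a warning and still counts as a
  replicate.
* A rank-sum comparison where every pooled value is identical returns p = 1
  with a degeneracy warning.
* Radius histograms use right-closed bins, so a `breaks = 3` split
  reproduces the ≤ 3 / > 3 strata exactly.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the planted-signal study at
the generator defaults against a 100-replicate null, and the null
calibration (all biases zero) over 100–200 generator seeds with 20
replicates each; calibration constrains the distribution of the real-vs-null
p-value, for which a modest ensemble per seed is sufficient. The
degree-preservation check uses the full 1,000-replicate ensemble on a
100-node, 300-edge graph.

## Known limitations

* The rank-sum test treats pooled null values as one exchangeable sample;
  values from the same replicate are not independent, which the pooled mode
  ignores (the `replicate_mean` mode avoids it at the cost of power).
* No weighted shortest paths or diffusion scores; interaction p-values gate
  edge retention but do not weight edges.
* No pathway enrichment statistics and no topology-aware crosstalk scores;
  the four-category classification is purely set- and edge-based.
* The double-edge-swap null preserves degrees only; clustering, assortativity
  and connectedness are free to change.
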