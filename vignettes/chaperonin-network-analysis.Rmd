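---
title: "Methods: chaperonin substrate classes on the metabolic reaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaperonin substrate classes on the metabolic reaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chapnet)
```

## The question and the model

Chaperonin (GroEL/GroES) substrates in *E. coli* are graded by how much
they need the chaperonin to fold: Class I (independent), II (partially
dependent) and III (obligate candidates) under the original proteome-wide
scheme, refined in vivo to Class I, II' and IV with an ambiguous III⁻
remainder. Many substrates are metabolic enzymes, which raises a
topological question: do the classes occupy different places on the
metabolic network?

`chapnet` operationalises "place" through the *reaction network*: nodes are
enzyme-catalysed reactions, and a directed edge runs from reaction A to
reaction B when at least one product of A is a substrate of B. Naively
applied, this rule is ruined by currency metabolites — ATP, NADH, water and
the like would connect nearly everything to nearly everything. The KGML
pathway files solve this upstream: each reaction element lists only the
curated, essential substrate–product pairs of the actual transformation,
so building edges from those pairs alone (`parse_kgml()` +
`build_reaction_network()`) excludes currency shortcuts without any
ad-hoc metabolite blacklist. Reversible reactions contribute their pairs
in both orientations at build time; the parser itself stays lossless.

All distance analyses need every node pair to be reachable, so the directed
graph is reduced by `to_undirected_lcc()`: drop direction (parallel edges
through different metabolites collapse to one unweighted edge, self-edges
are removed) and keep the largest connected component. A strongly connected
component of the directed graph would be the stricter choice but is
typically far too small to carry a comprehensive shortest-path analysis;
the undirected LCC trades edge direction for coverage.

Two class-stratified statistics describe the layout. With a central node
*o* and d(·,·) the unweighted shortest-path length, the
*distance-from-center profile* of a class C is

$$P_C(h) = \frac{1}{|C|}\sum_{x \in C} \delta\!\big(d(o,x) - h\big),$$

with δ the Kronecker delta (h = 0 is a legal bin: the center may belong to
C). The *within-class pairwise profile* is the analogous histogram over the
\(|C|(|C|-1)/2\) unordered member pairs; self-pairs are excluded and order
is irrelevant on an undirected graph. Both report mean and median — class
contrasts in the literature are quoted sometimes as one, sometimes as the
other.

The center defaults to pyruvate kinase. Pyruvate is the classic crossroads
metabolite (glycolysis, the citrate cycle, amino-acid and lipid
metabolism), gluconeogenesis is among the best-conserved, presumably
ancestral pathways, and the pyruvate-kinase node scores near the top of
every centrality measure on the real network. The b-numbers are
configurable (`select_center(net, center_genes = …)`, default pykF `b1676`
and pykA `b1854`) because "pyruvate kinase" names two isozymes; when
several nodes match, the highest-degree one wins, with lexicographic
tie-breaking so the choice is reproducible.

## Node measures and their conventions

`node_measures()` computes the four traditional per-node quantities, with
conventions chosen once and used everywhere:

* **degree** — neighbour count k.
* **closeness** — \((N-1) / \sum_{j \ne i} d(i,j)\), defined on the
  connected LCC only (a disconnected input is an error, not an NA).
* **betweenness** — endpoint-free counting over unordered pairs,
  \(\sum_{s \ne t \ne i} \sigma_{st}(i)/\sigma_{st}\), then divided by the
  maximum nodal value so the most central node scores exactly 1. This
  max-normalisation (rather than the conventional \((N-1)(N-2)/2\) factor)
  makes the ordered/unordered counting distinction irrelevant. When no
  node is interior to any geodesic (complete graphs) all values are 0.
* **clustering coefficient** — \(2M_i/[k_i(k_i-1)]\); degree-0 and
  degree-1 nodes are assigned 0 rather than NaN so per-class aggregation
  never silently drops nodes.

Rankings (`rank_of()`) are competition ranks on descending values: ties
share the smallest rank of their group.

## The statistical battery

Distances and measures are compared across classes with rank-based tests,
which is essential because shortest-path lengths are small integers with
massive ties:

* `kruskal_wallis()` — tie-corrected H with a χ² reference on
  (groups − 1) degrees of freedom. When every observation is identical the
  χ² form is 0/0; the package returns H = 0, p = 1 by convention.
* `wilcoxon_rank_sum()` — two-sided; exact enumeration when both groups
  have ≤ 10 untied observations, otherwise the tie-corrected normal
  approximation.
* `student_t()` — the classical pooled-variance form (not Welch), matching
  the named test in this literature. Zero pooled variance degenerates to
  p = 1 (equal means) or p = 0 (unequal).

The χ² approximation is knowingly coarse at very small samples: at 3 + 3
observations its p can sit ~0.05 from the exact permutation value, which
the test suite documents by asserting the exact value (0.1) from an
enumeration oracle alongside the approximate one; from 5 + 5 on the two
agree within 0.02. No multiple-testing correction is applied across the
measure-by-class table — the convention here is to report raw p-values.

`abundance_vs_distance()` groups per-gene emPAI abundances by the integer
distance of the encoding node from the center and applies Kruskal–Wallis
across bins. Being rank-based, the test is invariant to the log transform
used for display. Genes without abundance and abundances without a network
gene are dropped by intersection; a gene on several nodes takes its
minimum distance.

`conservation_degree()` scores each gene as \(S_i/S_{\mathrm{total}}\),
the fraction of surveyed species with at least one ortholog.
\(S_{\mathrm{total}}\) is always taken from the table itself (its species
columns, or an explicit override for long-format files), never hard-coded:
the published value 1,368 is a property of one KO snapshot.
`conservation_by_class()` reports class medians in class order so the
monotone trend can be read directly, and omits Class III⁻ under the
revised scheme by default — its chaperonin requirement is unclear — with
`include_ambiguous = TRUE` to keep it.

Two deliberately open readings are resolved as follows and flagged where
relevant: a node whose subunit genes span *different* classes within one
scheme keeps all labels (counted once per label, with a runtime warning);
and "all enzymes" backgrounds include the class members themselves, i.e.
overlapping populations, which matches how the published all-enzyme means
behave.

## What the synthetic generator emulates

The generator exists so that the entire pipeline — including the KGML
parser — runs and is testable without touching KEGG or KO. It plants
exactly the statistical structure the analysis is meant to detect:

* **`grow_network()`** adds nodes one at a time. Each newcomer anchors on
  an existing reaction drawn with weight ∝ birth-index^`recency_bias`
  (default 1) — the retrograde-expansion picture in which new enzymes
  preferentially extend recently created metabolites — and attaches its
  remaining `edges_per_new_node − 1` (default 3 − 1) edges to random
  neighbours of the anchor. Random-neighbour attachment is the classic
  local realisation of degree-preferential attachment, so hubs and high
  clustering emerge, while the uniform-in-recency anchor makes mean
  distances grow ≈ log N (the small-world regime) *and* places later-born
  nodes systematically farther from the origin. A pure global
  degree-preferential rule was evaluated first and rejected: it compresses
  a 600-node network into distance shells 2–3 with almost no
  birth-order/distance correlation, leaving nothing for the downstream
  analysis to recover. Defaults (600 nodes, 3 edges per newcomer) give
  ~1,800 edges and a mean center distance of ~3.7, close to the real
  615-node / 2,083-edge network and its all-enzyme mean of 3.58.
* **`assign_classes()`** classifies each node with probability
  `sum(class_fractions)` (default 0.19, mirroring the ~20% of enzymes that
  are substrates, split 0.05/0.07/0.07 as in the real class sizes), then
  orders the classified nodes by a noisy age score
  u = birth-rank + N(0, 1/`age_bias`) and cuts contiguous I | II | III
  bands sized by the fractions. Fractions are thus honoured exactly at any
  bias; `age_bias = 0` is exactly label–position independence; large bias
  approaches clean age bands while remaining probabilistic at the
  boundaries. The revised-scheme column is derived as the in-vivo
  reinvestigation reshaped the classes: I→I, II→II', III→IV with
  probability 0.8 else III⁻.
* **`make_ortholog_table()`** retains each gene in each of `n_species`
  (default 200) species independently with probability `retention[class]`
  (defaults 0.9/0.6/0.3; unclassified background 0.8), so class-mean
  conservation ratios estimate the retention parameters to within
  binomial error.
* **`make_abundance()`** draws log-normal values (log-mean 0, log-sd 1)
  independent of topology, so the abundance-versus-distance test is null
  by construction.
* **`write_kgml()`** encodes the grown network as a valid KGML document
  (node i produces compound C_i and consumes its earlier neighbours'
  compounds), so parse → build → LCC reproduces the network exactly —
  the end-to-end oracle for the IO layer.

Every stage derives its stream from `seed` with a fixed small offset per
stage, so one configuration reproduces all five inputs byte for byte, and
the generator restores the caller's RNG state.

What the generator does *not* emulate: stoichiometry, real compound
vocabulary, reaction reversibility patterns, the modular pathway
organisation of real metabolism, or any correlation between abundance and
class. Passing recovery tests therefore show that the pipeline detects
age-graded lateral placement and class-graded conservation when present;
they do not show that the real *E. coli* signal has the planted effect
size, and the generator's degree–age coupling is stronger than in the real
network (where degree barely separates the classes).

## Numerical choices and degenerate inputs

* Component ties in `to_undirected_lcc()` break toward the component
  containing the lexicographically smallest node id; center ties by degree
  then node id — all outputs are reproducible orderings.
* Profile proportions must sum to 1 (checked to 1e-9 in tests); profiles
  of an empty member set, pairwise profiles of fewer than two members,
  sources outside the network, unknown class labels, conflicting duplicate
  class rows, empty class tables, an empty species universe and < 2
  abundance bins are all hard errors rather than silent NAs.
* Gene identifiers are normalised once at the boundary (lower-case,
  organism prefix stripped), so b-number comparisons are exact thereafter.
* Genes with zero ortholog presences are representable: the readers carry
  the full gene and species universes as attributes, so a ratio of 0 is a
  value, not a missing row.

## Problem sizes

The test suite and acceptance script run entirely on generated data at the
study conditions: 600-node networks (20 replicate seeds for the
distance-ordering recovery rate), 200-species ortholog tables,
shortest-path checks against a Floyd–Warshall oracle on 50 random graphs
of ≤ 60 nodes, betweenness against exhaustive path enumeration on graphs
of ≤ 12 nodes, and 1,000-replicate null simulations for the
Kruskal–Wallis type-I error. These sizes make every oracle exact or
near-exact while keeping a full run in the order of a minute.

## Known limitations

* Edge direction is discarded before all distance analyses; pathway
  irreversibility is not respected in shortest paths.
* Reproducing the published node and edge counts exactly depends on the
  KEGG snapshot and on how reactions shared across pathway maps are
  merged (here: by reaction id); the published p-values likewise belong to
  the 2011 snapshots.
* Betweenness is exact, not approximated — fine at N ≈ 600, slow far
  beyond.
* The package reads file snapshots only; there is no live KEGG/KO access.
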