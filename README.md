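# chapnet

Where do chaperonin-dependent enzymes sit in a metabolic network?

In *Escherichia coli* the chaperonin GroEL/GroES (GroE) folds a sizeable set
of substrate proteins, many of them metabolic enzymes. Substrates are graded
by how much they need the chaperonin — under the original proteome-wide
scheme Class I (independent), II (partially dependent) and III (obligate
candidates), and under the in-vivo revised scheme Class I, II' and IV, with
an ambiguous III⁻ remainder. `chapnet` implements the network analysis that
asks whether these classes occupy different territory on the metabolic
reaction network: enzymes as nodes, shared essential substrate–product
metabolites as edges, and chaperonin requirement as the grouping variable.

The package is aimed at systems-biology analysts who want the full pipeline
— from KEGG KGML pathway files to class-stratified statistics — as plain,
pipeable R functions returning tibbles.

## What it computes

* **Network construction** — [KGML](https://www.kegg.jp/kegg/xml/) parsing
  into reactions with curated substrate–product pairs; projection to the
  reaction-adjacency graph (edge A→B when a product of A is an essential
  substrate of B, so currency metabolites such as ATP or NADH cannot create
  shortcuts); reduction to the undirected largest connected component (LCC)
  on which every node pair has a finite distance.
* **Distance profiles** — for a class C with members x and a central node o
  (pyruvate kinase by default), the distance-from-center profile

  P_C(h) = (1/|C|) Σ_{x∈C} δ(d(o, x) − h),

  where d is the unweighted shortest-path length and δ the Kronecker delta,
  together with the within-class pairwise profile over the |C|(|C|−1)/2
  unordered member pairs.
* **Traditional node measures** — degree k_i; closeness (N−1)/Σ_j d(i,j);
  betweenness Σ_{s≠t≠i} σ_st(i)/σ_st normalised by its maximum over nodes;
  clustering coefficient 2M_i/[k_i(k_i−1)].
* **Class statistics** — Kruskal–Wallis across classes, Wilcoxon rank-sum
  and pooled-variance Student's t between two groups, plus an
  abundance-versus-distance test (emPAI values grouped by distance bin).
* **Conservation** — the degree of conservation S_i/S_total from an
  ortholog-presence table (S_i = species with ≥1 ortholog of gene i),
  compared across classes.
* **Synthetic data** — a seeded generator for every input the pipeline
  takes: a connected network grown by sequential expansion (mean distances
  grow ≈ logarithmically with size), age-biased class labels,
  class-dependent ortholog retention, and position-independent log-normal
  abundances, plus a KGML writer so the whole pipeline can be exercised
  end-to-end without any database download.

## Worked example

A complete synthetic study at the default conditions (600 enzymes, strong
age bias, retention 0.9/0.6/0.3):

```r
library(chapnet)

cfg <- synthetic_config(seed = 1)
net <- grow_network(cfg)
net
#> <reaction_network> 600 nodes, 1794 undirected edges (largest connected component)

classes <- assign_classes(net, cfg)
ann     <- annotate_nodes(net, classes, scheme = "kerner")
class_counts(ann)
#> # A tibble: 3 × 2
#>   class     n
#>   <chr> <int>
#> 1 I        33
#> 2 II       47
#> 3 III      46

center <- select_center(net, "b0000")
dmap   <- bfs_distances(net, center)
glance(distance_from_center_profile(dmap, class_members(ann, "III")))
#> # A tibble: 1 × 4
#>       n  mean median kind
#>   <int> <dbl>  <dbl> <chr>
#> 1    46  4.20      4 distance from center
glance(distance_from_center_profile(dmap, class_members(ann)))
#> # A tibble: 1 × 4
#>       n  mean median kind
#>   <int> <dbl>  <dbl> <chr>
#> 1   600  3.72      4 distance from center

orth <- make_ortholog_table(classes, cfg)
conservation_by_class(conservation_degree(orth), classes, "kerner")
#> <conservation_by_class>
#> # A tibble: 3 × 4
#>   class     n median  mean
#>   <fct> <int>  <dbl> <dbl>
#> 1 I        33  0.9   0.898
#> 2 II       47  0.615 0.612
#> 3 III      46  0.295 0.291
#> Kruskal-Wallis: H = 110.246, p = 1.149e-24
```

Read: obligate-class (III) enzymes average 4.20 steps from pyruvate-kinase
territory against 3.72 for all enzymes — later-acquired enzymes sit at the
network's edge — and their genes are retained in far fewer species (mean
conservation 0.29 vs 0.90 for Class I), the planted evolutionary signal
recovered by the analysis. `autoplot()` on any profile or conservation
result draws the corresponding histogram or boxplot, and
`run_pipeline(cfg, dir)` executes the whole chain from a written KGML file
through every statistic, leaving TSV reports in `dir`.

Real data enter through the same surface: `parse_kgml()` on KEGG pathway
files (or `read_edge_list()` on a published edge list),
`read_class_table()`, `read_ortholog_table()` and
`read_abundance_table()`.

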