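# ucattractor

Phylostratum-resolved analysis of the **unicellular (UC) attractor** in
cellular networks.

Animal genes carry an evolutionary age: phylostratigraphy assigns each gene
to the oldest clade with a detectable ortholog, here seventeen strata from
1 (cellular organisms) to 17 (Hominidae). Genes of strata 1–3 predate
multicellularity ("UC genes") and form the dense core of the protein
interaction network, while young genes sit at the periphery. The *UC
attractor* is the tendency of random interaction activity — and of cancer
expression programs — to drift toward that ancient core. `ucattractor`
gives researchers in network and cancer evolution a self-contained toolkit
to quantify this:

- **Interactome input** — STRING-style weighted edge lists, filtered at
  confidence strictly above 0.5, plus gene→stratum maps, gene-set flags
  (e.g. zinc-finger C2H2 repressors, IPR036236) and GO-style DAGs with
  annotation propagation (a gene belongs to a term if annotated to the term
  or any descendant).
- **Centrality profiles** — degree, closeness (reciprocal sum of hop
  distances within a component) and betweenness (Brandes semantics),
  averaged per stratum.
- **Random-walk simulation** — ensembles of uniform walks (default 10,000
  repeats, lengths 5–10,000) started in the youngest stratum; endpoint
  counts per stratum, normalized by stratum gene number. The closed-form
  anchor is the stationary law π(v) = deg(v)/2|E| of a walk on a connected
  non-bipartite graph.
- **Expression folds by stratum** — quantile normalization + log2, per-gene
  case−control folds, stratum-binned profiles with optional gene-family
  exclusion, and analysis-of-means (ANOM) decision limits
  x̄ ± h·s_p·√(1/nᵢ − 1/N).
- **Contrast-test enrichment** — per GO term, fold difference = category
  mean − total mean, 20,000 Monte-Carlo samplings without replacement,
  add-one two-tailed p-values, Benjamini–Hochberg q-values.
- **Synthetic generators** — age-layered core-periphery networks,
  stratified two-group expression with planted fold gradients, annotated
  DAGs with planted enrichment; every analysis is testable against a known
  ground truth without downloads.

Everything is data-frame-first and pipe-friendly: readers return tidy
tibbles or light S3 objects with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` charts.

## Worked example

Generate an age-layered interactome (12 genes per stratum, preferential
attachment), profile it, and run the walk ensemble:

```r
library(ucattractor)
library(dplyr)

gen <- gen_network(n_per_stratum = 12, m = 3, seed = 1)
gen$network
#> <interaction_network> 204 nodes, 606 edges (score > 0.5)
#>   dropped: 0 below threshold, 0 self-loops, 0 duplicates

stratum_summary(node_centrality(gen$network), gen$strata) |>
  filter(measure == "degree") |> head(3)
#>   stratum measure  mean   sem     n
#> 1       1 degree  20.8   2.20    12
#> 2       2 degree  10.6   1.33    12
#> 3       3 degree   8.67  1.42    12
```

Mean degree falls from 20.8 in stratum 1 to 3.1 in stratum 17: the old
core is an order of magnitude denser than the young periphery. Walks
started in stratum 17 end up there:

```r
d <- run_walk_ensemble(gen$network, gen$strata, walk_length = 200,
                       n_repeats = 10000, start_stratum = 17, seed = 2)
head(as_tibble(d), 5)
#>   stratum n_genes raw_count normalized
#> 1       1      12      2076      173
#> 2       2      12      1051       87.6
#> 3       3      12       862       71.8
#> 4       4      12       773       64.4
#> 5       5      12       544       45.3
```

A fifth of all 10,000 walks end in stratum 1 alone; per-gene endpoint
frequency declines monotonically with stratum age (Spearman r = −0.95
against stratum index) — the UC-attractor signature. `autoplot(d)` draws
the endpoint profile.

Enrichment on a synthetic DAG with one planted 50-gene term shifted by
+1 sd in a 2000-gene universe:

```r
genes <- sprintf("x%04d", 1:2000)
go   <- gen_go(genes, n_terms = 30, size_range = c(30, 80),
               planted_sizes = 50, seed = 5)
vals <- gen_go_values(go$dag, genes, planted = go$planted, shift = 1, seed = 6)
run_enrichment(vals, go$dag, min_genes = 21, n_samples = 20000, seed = 7) |>
  head(3)
#>   term        n_genes category_mean fold_difference   p_value q_value
#> 1 T_planted_1      50         1.12            1.11  0.0000500 0.00155
#> 2 T020             72         0.428           0.415 0.000300  0.00465
#> 3 T005             53         0.249           0.236 0.0851    0.528
```

The planted term tops the ranking with fold difference 1.11 (truth: +1)
and q ≈ 0.002; T020 also flags because it inherits planted genes through
DAG propagation.

The whole analysis — network, centrality, walk sweep, folds, profile,
ANOM, enrichment — runs from one configuration:

```r
manifest <- run_attractor_pipeline(list(seed = 1), out_dir = "demo_run")
```

which writes nine TSV tables and a JSON manifest with md5 digests; rerunning
with the same seed reproduces every file byte for byte.

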