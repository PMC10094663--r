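---
title: "Detecting the unicellular attractor: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the unicellular attractor: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucattractor)
library(dplyr)
```

## The question

Animal genomes are layered by evolutionary age. Phylostratigraphy assigns
each gene to the oldest clade in which an ortholog is detectable — here
seventeen strata from 1 (cellular organisms) to 17 (Hominidae), with strata
1–3 (before Metazoa) called *unicellular* (UC) and 4–17 *multicellular*
(MC). In protein-interaction networks the oldest genes sit in a densely
connected core while young genes occupy the periphery. `ucattractor`
implements a suite of analyses built on that observation:

1. **Centrality profiling** — degree, closeness and betweenness of every
   protein in a confidence-filtered interactome, summarized per stratum.
2. **Random-walk endpoint simulation** — uniform random walks started among
   the youngest proteins; if network activity drifts toward the ancient
   core (the *UC attractor*), walk endpoints concentrate there.
3. **Stratified expression folds** — quantile-normalized single-cell
   expression, per-gene log2 case/control folds, stratum-binned profiles
   and analysis-of-means (ANOM) decision limits.
4. **Contrast-test enrichment** — for each term of a GO-style DAG, the
   difference between the category's mean fold and the whole-dataset mean,
   with Monte-Carlo significance and false-discovery-rate q-values.
5. **Synthetic data generators** that plant each of these signals, so every
   claim is testable against a known ground truth without downloads.

## Network model and centralities

The interactome is an undirected graph read from a STRING-style edge list.
Edges are kept when their confidence score is *strictly greater than* the
threshold (default 0.5, the top half of the confidence range); self-loops
are dropped and symmetric duplicates collapsed. Scores on the STRING 0–1000
integer scale are detected by their magnitude and divided by 1000.

Confidence acts only as a filter: path lengths are hop counts.
For a node $v$,

* degree is the number of retained neighbours;
* closeness is $1 / \sum_u d(v,u)$ with the sum over nodes reachable from
  $v$ — the raw reciprocal-of-sum form, computed within $v$'s connected
  component because the sum is undefined for unreachable pairs. Isolated
  nodes get closeness 0. A size-normalized variant (multiplying by the
  component size minus one) is available behind
  `normalize_closeness = TRUE`, default off, because the raw form is the
  definition used throughout;
* betweenness counts all-pairs shortest-path traffic through $v$, each
  unordered pair once, endpoints excluded, with equal-length paths sharing
  credit fractionally (the standard Brandes semantics). The verbal
  definition "number of shortest paths passing through" is ambiguous under
  ties; fractional credit is the convention of every modern network tool
  and is what the test oracles implement independently.

`stratum_summary()` averages any per-node measure within strata, reporting
mean, standard error and $n$; nodes missing from the stratum map are
excluded from summaries (their count is kept as an attribute) but remain in
the graph.

## The random-walk attractor simulation

A walk starts at a node drawn uniformly from the start stratum (default 17,
the youngest), and at each of `walk_length` steps moves to a uniformly
chosen neighbour; returning to previously visited nodes is allowed. Only
the *endpoint* is tallied. An ensemble (default 10,000 repeats) yields
per-stratum endpoint counts, normalized by the number of stratum genes
present in the filtered network so that strata of different sizes are
comparable. The denominator is network-resident genes rather than a
genome-wide count because that keeps the quantity self-contained; an
external per-stratum gene-count table can be supplied instead
(`stratum_sizes`).

The mathematical backbone: on a connected non-bipartite graph the endpoint
law of a long uniform walk converges to the degree-proportional stationary
distribution $\pi(v) = \deg(v) / 2|E|$. The per-stratum normalized
frequency therefore converges to (mean stratum degree)$/2|E|$ — walks
concentrate wherever degree concentrates, which on an age-layered network
is the ancient core. This closed form is the package's primary oracle: the
tests compare simulated endpoint distributions against it directly, and the
`walk_length_sweep()` convergence diagnostic (total-variation distance
between successive lengths, default grid 5–10,000 steps) shows
stabilization after a few tens of steps.

Walks are generated in C++ with a counter-based RNG (splitmix64 streams
keyed by master seed and repeat index). Each repeat has its own substream,
so the tally is bit-reproducible for a given seed and independent of
execution order. Bounded draws use rejection sampling, so no modulo bias
enters. An isolated start node terminates the walk in place and is counted
in `n_dead_end`; this cannot occur in a graph built from an edge list but
is defined for completeness.

## Expression folds across strata

Expression matrices (genes × cells, two cell groups) are quantile
normalized: every cell's sorted values are replaced by the across-cell mean
of sorted values, ties within a cell receiving the mean of their reference
quantiles, followed by $\log_2(x + 1)$ (the pseudocount is skipped via
`offset = 0` for continuous intensities). The per-gene fold is the case
mean minus the control mean of the log values — positive means up in
cancer/invasive/polyploid cells. The source text describing the
subtraction order is internally inconsistent with its own figure labelling;
the package fixes fold = case − control and records the orientation in the
output's metadata.

`stratum_profile()` averages folds (or levels) in stratum bins. The default
bins $\{1\},\{2\},\{3\},\{4\text{–}6\},\{7\text{–}9\},\{10\text{–}17\}$
mirror the three phases seen in evolutionary fold profiles — an ancient
peak, an early-metazoan plateau, a recent decline — and any partition of
1..17 may be supplied (e.g. `as.list(1:17)` for single-stratum resolution).
An optional exclusion set (typically the ZF-C2H2 zinc-finger repressors,
InterPro IPR036236) produces a parallel profile with the flagged genes
removed, so their influence can be displayed side by side. Empty bins are
reported with $n = 0$ and an undefined mean rather than dropped.

ANOM decision limits for stratum means are
$\bar{x} \pm h\, s_p \sqrt{1/n_i - 1/N}$, with $s_p$ the pooled
within-stratum standard deviation and, by default,
$h = t_{1-\alpha/(2k),\,N-k}$ — a Bonferroni-adjusted quantile over the $k$
strata. The exact ANOM variant behind the published charts is not
documented, so a Monte-Carlo calibration mode (`method = "mc"`) is provided
that simulates the null maximum standardized deviation and respects the
correlation between stratum deviations; the Bonferroni default is slightly
conservative, which the calibration tests quantify (family-wise null flag
rate below $\alpha$). Strata with fewer than two genes are excluded with a
warning. Zero-variance genes are retained: their fold is defined and no
filtering rule is part of the method.

`stratum_composition()` reports the share of a gene set falling in each
stratum — by default (set genes in stratum)/(set size); normalizing by
stratum totals is a flag — plus the Spearman rank correlation of that share
with the stratum index, the standard summary of how UC-biased a gene set
is.

## The contrast test

For each term of the DAG, annotations are first propagated upward: a gene
belongs to a term if it is annotated to the term or to any descendant.
Propagation runs once in topological order and guarantees the superset
property (a parent's gene set contains every child's). The term's measured
genes are intersected with the value table; terms below the minimum size
(default 21, i.e. the ">20 genes" filter used for biological processes; 11
for the ">10 genes" cell-component filter) are skipped.

The statistic is the *fold difference*: the category mean minus the mean of
all measured genes. Significance comes from 20,000 random gene samples of
the category's size, drawn without replacement from the full measured set
(the pool is restored between samples; category genes are not excluded from
the pool, since no exclusion is part of the procedure). The two-tailed
p-value uses the add-one estimator
$p = (1 + \#\{|\bar{x}_{sample} - \bar{x}| \ge |\bar{x}_{cat} - \bar{x}|\})
/(1 + n_{samples})$, which can never return an exact zero. Ties count as
exceedances, matching permutation-test convention; the enumeration oracle
in the tests uses the same convention, and the two agree within binomial
error on every small universe. q-values are Benjamini–Hochberg step-up
(`stats::p.adjust`), with Benjamini–Yekutieli behind a flag; the baseline
"total gene set" is the measured genes, not the annotated universe.

## What the generators emulate — and what they do not

* `gen_network()` grows nodes in stratum order 1→17 under preferential
  attachment (each new node attaches `m = 3` edges with probability
  proportional to degree + 1) or duplication–divergence. Early nodes
  accumulate degree, planting the old-core/young-periphery gradient that
  drives both the centrality profile and the walk attractor. Edge
  confidences are drawn above 0.5 so fixtures survive the filter;
  `n_noise_edges` adds sub-threshold records to exercise it. No attempt is
  made to match human stratum sizes or STRING's degree distribution
  quantitatively.
* `gen_expression()` draws each gene's log2 baseline from its stratum's
  mean (default $8 - 0.15(s-1)$: ancient genes more expressed) plus a
  gene-level dispersion (`baseline_sd = 2` log2 units, the orders-of-
  magnitude spread of real transcriptomes), then shifts case cells by a
  per-stratum effect $\delta(s)$ — the planted "gradual atavism" gradient —
  under lognormal or negative-binomial noise.
* `gen_go()` builds a random acyclic term graph (every non-root term gets
  1–2 shallower parents) with random direct annotations, plus optional
  planted leaf terms of exact size whose genes `gen_go_values()` shifts.

One identifiability point deserves emphasis, because it bounds what a
passing test can show about real data. Quantile normalization forces every
cell onto a common distribution, so (a) the genome-wide mean of any
case-versus-control shift is removed by construction, and (b) any component
of the shift that is predictable from a gene's rank within a cell is
cancelled. The recoverable quantity is the *gradient* — deviations of
$\delta(s)$ around its mean, for genes whose rank is not determined by
their stratum. The generator's baseline dispersion provides that
decoupling; the recovery tests accordingly compare the fitted profile to
the centered gradient $\delta(s) - \bar{\delta}$ and accept up to ~30%
slope attenuation from the residual stratum–baseline correlation. Real
tumour data have the same property: a truly uniform genome-wide
upregulation would be invisible to this (or any) rank-based normalization.

The generators restore the caller's RNG state and are seed-deterministic;
tests verified they do not disturb the ambient stream.

## Pipeline and reproducibility

`run_attractor_pipeline()` runs generation → centrality → walk sweep →
normalization/folds → profiles/ANOM → enrichment from one configuration
(nested list or YAML file; YAML is the package's configuration format) and
writes TSV tables plus a JSON manifest with per-file md5 digests and row
counts. Reals are written with fixed 9-decimal formatting so byte-level
reproducibility is meaningful; stage seeds are derived from the master seed
by stable string hashing, making every stage independently re-runnable and
the whole run byte-identical under a fixed configuration.

```{r demo, eval = FALSE}
out <- tempfile("ucdemo")
manifest <- run_attractor_pipeline(list(seed = 1), out_dir = out)
readr::read_tsv(file.path(out, "enrichment.tsv"))
```

## Problem sizes used in the checks

The shipped verification suite works at desk scale, chosen once as the
smallest sizes at which each phenomenon is unambiguous: 100 random graphs
of up to 50 nodes for exact centrality equivalence; a 204-node age-layered
network with 100,000 walks of 1000 steps for the stationary law
(total-variation target 0.02); 20 generator seeds for the attractor rank
correlation; enumeration universes of 8–12 genes and 2000 null categories
at the full 20,000-sample depth for the contrast test; 50 planted and 100
null seeds at 2000 samples per term for enrichment recovery and FDR
control; 1020 genes × 80 cells for gradient recovery; 300 null and 60
power simulations for ANOM. `scripts/acceptance.R` recomputes the headline
numbers from scratch at these sizes.

## Known limitations

* The package consumes a precomputed gene→stratum map; it does not date
  genes from sequence orthology.
* Identifier spaces are assumed shared between the network, the stratum
  map and the expression tables; no identifier-mapping service is bundled.
* Walks are plain uniform walks — no restarts, no confidence-weighted
  steps — because that is the model being studied.
* The enrichment statistic is the mean-contrast test only; it is not a
  hypergeometric over-representation test nor a running-sum GSEA, and the
  moderated statistics of differential-expression frameworks are out of
  scope (only quantile normalization and the log2 step are used).
* ANOM limits assume approximately normal stratum means (large per-stratum
  $n$); the Monte-Carlo mode relaxes the multiplicity approximation but
  not that assumption.
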