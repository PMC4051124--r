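---
title: "Biological distance, gene-specific connectomes and candidate prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological distance, gene-specific connectomes and candidate prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneconnectome)
```

## The model

Causal genes of a single phenotype tend to be functionally close to each
other: they sit in the same pathways, complexes and regulatory
neighbourhoods. `geneconnectome` operationalizes this premise as a
*biological distance* on a genome-wide weighted graph. Nodes are genes;
an edge joins two genes with a direct (physical) interaction, weighted by
a confidence score $s \in (0, 1]$ taken from an interaction database.
Inverting the score turns confidence into a direct distance, and the
biological distance between any two genes $a, b$ is the weight of the
minimal-weight path between them:

$$ d(a, b) \;=\; \min_{\text{paths } a \to b} \; \sum_{(u,v) \in \text{path}} \delta(u, v), \qquad \delta(u,v) = 1/s_{uv}. $$

The *gene-specific connectome* of a core gene $g$ is the list of all
other genes ordered by $d(g, \cdot)$, annotated with rank, connectivity
p-value, best reciprocal p-value (BRP), the ratio of the distance to the
genome-wide median and mean distance from $g$, a sphere (coarse
percentile bin), the predicted route (the genes along the minimal path),
degrees of separation (the route's edge count) and the full gene name.
Candidate lists from high-throughput experiments are prioritized by
building the connectome of each core gene and sorting the candidates by
distance, p-value or BRP — globally (each candidate paired with its best
core) or separated by core gene.

## Score inversion

Only the fact of inversion is canonical; the functional form is a design
choice. Two forms are implemented:

* **reciprocal** (default), $\delta = 1/s$: unbounded above, penalizes
  weak interactions super-linearly. A chain of two $s = 0.9$ edges
  ($\delta = 2.22$) beats one $s = 0.25$ edge ($\delta = 4$), which
  matches the intuition that two strong interactions are better evidence
  of functional proximity than one weak one, and reproduces the heavy
  right tail seen in connectome distance distributions.
* **complement**, $\delta = 1 - s + \varepsilon$ with
  $\varepsilon = 10^{-6}$: bounded in $(0, 1]$; the epsilon keeps
  perfect-confidence edges at positive length so every edge traversal
  costs something. Provided for sensitivity analysis; under either form
  distance is strictly decreasing in score, so single-edge orderings
  agree.

## Connectivity p-values and BRP

The connectivity p-value of target $t$ in the connectome of $g$ is its
rank percentile,

$$ p_g(t) = \mathrm{rank}_g(t) / N, $$

where $N$ is the number of non-core genes and ranks order targets by
(distance, symbol). This is the minimal definition with an exactly
uniform null: a target drawn uniformly at random has
$p \sim \mathrm{Uniform}\{1/N, \ldots, 1\}$, which the test suite checks
with a Kolmogorov–Smirnov statistic against the 1% critical value at
1000 draws. Unreachable targets get $p = 1$; a core queried against its
own connectome gets the floor $1/N$.

The two directions are not symmetric: a hub gene is close to everything,
so $p_{\mathrm{hub}}(t)$ is large even for its genuine partners, while
$p_t(\mathrm{hub})$ is small. The **best reciprocal p-value**
$\mathrm{BRP}(a,b) = \min\{p_a(b),\, p_b(a)\}$ compensates for central
and isolated genes and is symmetric by construction; it is less
stringent than either directed p-value and correspondingly more prone to
false positives, which is why `distance` stays the default
prioritization metric.

Per-patient p-values for the same gene can be combined with
`combine_pvalues()`: the default is the plain product of the rank
percentiles (a descriptive score, not itself calibrated), with Fisher's
$\chi^2_{2k}$ combination as the calibrated alternative. Both are
monotone in $\sum \log p_i$ and therefore order equal-length lists
identically.

## Annotation conventions

* **Ties** in distance are broken alphabetically by target symbol, and
  ranks are ordinal $1..N$ after that ordering, so output tables are
  bit-reproducible.
* **Unreachable targets** (other components) rank after all reachable
  ones, with infinite distance, empty route, `NA` degrees and ratios,
  and $p = 1$. Ratios to the median/mean distance are computed over
  finite distances only — a single disconnected gene would otherwise
  destroy both.
* **Sphere** is the rank decile, $\lceil 10\,\mathrm{rank}/N \rceil$:
  the simplest coarse percentile binning, chosen because nothing finer
  is canonical.
* **Degrees of separation** is the edge count of the reported
  minimal-*distance* route, not an independently minimized hop count;
  with reciprocal inversion every edge costs at least 1, so the two
  rarely differ and the reported number always describes the same route
  the table prints.
* **Missing frequency fields** in variant tables parse as 0: absence of
  a database record must not silently discard a rare variant.
* Symbols are upper-cased at read time; candidate resolution tries exact
  canonical match, then the alias table, then case normalization, and
  reports unresolvable symbols rather than erroring — real exome lists
  routinely contain symbols absent from interaction databases.
* Duplicate interaction rows keep the **maximum** score (hence the
  shortest distance): conservative toward connectivity and
  deterministic under row shuffling.

## The variant filter

The pre-prioritization whole-exome filter keeps a variant iff

1. its effect class is nonsynonymous (rule i),
2. its frequency is strictly below 1% in *each* of the two population
   databases (rule ii) — requiring both is equivalent to applying the
   cut to the maximum across databases, and
3. at most 0.6% of patients from other disease cohorts carry it
   (rule iii; the boundary itself is kept, "more than 0.6%" being the
   drop condition). This batch filter removes recurrent artefacts and
   hypermutable genes.

The kept *set* is order-independent (the rules are conjunctive); only
the per-rule drop attribution follows the i–iii order.

## What the synthetic generator emulates — and what it does not

`generate_network()` produces an Erdős–Rényi background
(`n_genes = 500`, `edge_prob = 0.02`, scores uniform on 0.15–0.40) plus
a planted, fully connected pathway module (10 genes, scores uniform on
0.70–0.95). The module emulates the premise above: a phenotype's pathway
is a small, high-confidence functional neighbourhood. The score ranges
are disjoint so module edges are always shorter than background edges —
an idealization that makes recovery guarantees analytic rather than
statistical. Defaults were fixed once, as a caricature of a sparse
interactome (mean background degree ≈ 10) with a dense disease module,
and the benchmark conditions (500 genes, a 10-gene module, 200
candidates, 100 replicates) match those the test suite and the
acceptance script use throughout.

`generate_variant_table()` builds a 400-variant candidate table of known
composition — 25% synonymous, 25% common (population frequency ≥ 2%),
10% cohort-frequent (> 0.6%), the rest rare nonsynonymous, plus one
guaranteed-surviving causal missense variant — so the filter's kept
count is checkable exactly, and the post-filter gene count (~160) is of
the same order as the ~300 filtered genes per patient that motivated the
method. Non-causal variants are drawn from outside the planted module:
the benchmark asks whether *one* causal pathway gene is recovered from
background candidates, and stray rare variants in other module genes
would contaminate that question.

The degraded-module null (`degrade_module = TRUE`) plants no clique at
all: the designated module genes receive only ordinary background edges.
This is deliberate. Keeping the clique but lowering its scores to the
background range would still leave the causal gene a direct neighbour of
the core — structure, not chance — whereas the null the recovery
benchmark needs is "no planted signal whatsoever", under which the
causal gene's mean rank is half the candidate count. A `hub_gene` option
wires one background gene to 30% of the genome with high scores, to
reproduce the observation that a highly central core gene discriminates
poorly.

What the generator does **not** emulate: scale-free degree
distributions, correlated edge scores, overlapping pathways, or score
noise between the module and background ranges. Passing the recovery
benchmark therefore shows the machinery is correct and well-calibrated
under idealized conditions; it does not bound performance on a real
interactome, where module edges and background edges overlap in
confidence.

## Numerical choices and degenerate inputs

Shortest paths are computed with Dijkstra's algorithm (all edge weights
are positive by construction) via igraph; the test suite checks the
distances against two independent oracles — exhaustive simple-path
enumeration on graphs of ≤ 10 nodes and Bellman–Ford edge relaxation on
graphs of ≤ 30 nodes — to $10^{-9}$ over 100 seeded random graphs, and
checks that every reported route sums to its reported distance. Empty
interaction sets are an error (a network must be non-empty); empty
candidate *files* are an error at the CLI but an empty kept set from the
variant filter is not. All generator randomness flows through a single
integer seed, and identical seeds give byte-identical output TSVs.

## Known limitations

* The p-value is a rank percentile, a descriptive calibration device; it
  is not a test of functional association, and combined per-patient
  values should be read as rankings, not significance statements.
* Global mode reports each candidate once, with its best core; the
  alternative (once per core) is available as `per_core` mode.
* The route reported for tied shortest paths is one deterministic
  representative, not an enumeration of all minimal routes.
* Only a single confidence score per edge is supported — no edge types,
  directions or layers.
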