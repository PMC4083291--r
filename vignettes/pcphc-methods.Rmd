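---
title: "Correlation-proximity clustering and order-preserving pattern mining"
author: "pcphc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-proximity clustering and order-preserving pattern mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcphc)
```

## The problem

A gene expression matrix records a measured level $w_{ij}$ for gene $i$
under sample/condition $j$ — raw intensities, or two-channel log-ratios
$\log_2(C/R)$ of a test over a reference level. Genes acting in a common
process tend to co-vary across conditions, but their absolute levels and
dynamic ranges differ, so co-membership shows up as *correlation* and,
more stringently, as a *shared linear ordering* of column values: for a
coherent gene set there is an ordering of a subset of conditions along
which every member's expression increases. A gene set together with such
a column order is an order-preserving bicluster; here we call it a
pattern.

`pcphc` mines such patterns in two stages:

1. **Proximity clustering.** The proximity of two gene profiles is the
   Pearson correlation
   $$ r(a, b) = \frac{\sum_j (a_j - \bar a)(b_j - \bar b)}
      {\lVert a - \bar a \rVert \, \lVert b - \bar b \rVert}, $$
   turned into the dissimilarity $d = 1 - r$. Genes are agglomerated
   bottom-up under average linkage: the two current groups with the
   smallest mean cross-group distance
   $$ D(G_1, G_2) = \frac{1}{|G_1| |G_2|}
      \sum_{i \in G_1} \sum_{j \in G_2} d_{ij} $$
   merge next, producing a dendrogram that is cut into $k$ flat
   clusters.

2. **Seed-Augment growth.** Each cluster seeds a pattern that is grown
   to maximality by alternating *column expansion* (insert the
   best-supported absent column at its best position) and *row
   expansion* (absorb every outside gene whose row supports the current
   order), until no admissible addition remains.

### Assumptions

- Rows are complete and finite; correlations require at least two
  samples and nonzero row variance (constant genes are rejected or
  dropped explicitly, never propagated as `NaN`).
- Anticorrelated genes are treated as *dissimilar* ($d = 1 - r$ spans
  $[0, 2]$); the method looks for a shared ascending order, not for
  mirror-image profiles.
- Patterns are strictly monotone along their column order up to the
  `e_max` tolerance; shift/scale pattern models and negative
  (descending) co-patterns are out of scope.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `e_max` | 0 | tolerated fraction of order-violating adjacent column pairs per row; 0 demands strict increase |
| `h_min` | 0 | minimum fraction of pattern rows that must support a column insertion; 0 means *all* rows |
| `tie_tol` | 1e-9 | values closer than this are ties; a tie violates a strict order |
| `k` | `floor(n/3)` | number of dendrogram clusters used as seeds |
| `seed_support` | 0.85 | consensus fraction during seed distillation (below) |

`e_max` and `h_min` are both fractions in $[0,1]$ and both default to 0,
the strict setting under which every emitted pattern is a perfect
order-preserving submatrix and `pattern_quality()` is identically 1. A
literal reading of `h_min = 0` ("zero rows must support") would admit
every column and make growth meaningless, so 0 is interpreted as the
all-rows rule; any positive value is the usual fractional quorum
`ceiling(h_min * n_rows)`.

`tie_tol` exists because floating-point equality is meaningless: two
values closer than `tie_tol` cannot be ordered, and strictness is the
conservative reading of an "ordering relationship". It is a numerical
guard, not a biological smoothing parameter — it should stay far below
the data's noise scale.

`k` defaults to the largest value keeping the mean cluster at three or
more genes, since a seed needs at least a couple of rows to define a
consensus order; it is the main resolution knob and worth varying in
practice.

## From cluster to seed

A dendrogram cluster is rarely a clean pattern: average-linkage clusters
carry the odd stray gene, and under `e_max = 0` a single stray poisons
the all-rows rule for every subsequent column insertion. Seeds are
therefore *distilled*:

1. `derive_seed_order()` ranks all columns by their mean over the
   cluster rows — the cluster's consensus order.
2. The adjacent pair of that order supported by the most cluster rows
   becomes the initial order, and the seed rows shrink to its
   supporters.
3. The order is extended greedily: the insertion (column, position) with
   the most support among current seed rows is accepted while that
   support is at least `seed_support` of them; the rows shrink to the
   supporters after each acceptance.

The default `seed_support = 0.85` separates two regimes. An insertion of
an unrelated background column is supported by roughly a
Binomial$(n, 1/2)$ share of rows (one new adjacency constraint per row,
two in the interior), whose maximum over the few dozen candidate
insertions sits near 0.75–0.8 of rows for typical seed sizes. A genuine
pattern column is supported by every coherent row and diluted only by
strays, which in practice are under ~20% of an average-linkage cluster,
leaving support near 0.9. The fraction 0.85 sits between the two; the
strays themselves fail successive insertions independently and wash out
of the seed within a few steps. Strict `grow_to_maximal()` expansion
then starts from rows that all support a long order.

## Numerical and determinism choices

- Correlations are clamped to $[-1, 1]$ after the division; floating
  point overshoot would otherwise break the proximity-matrix invariant.
- Average linkage is maintained with Lance–Williams updates
  ($d_{(ij)k} = (n_i d_{ik} + n_j d_{jk}) / (n_i + n_j)$), which equals
  the full cross-group mean in exact arithmetic; the test suite holds
  the implementation to a from-scratch recomputation oracle at 1e-12.
- Merge ties are broken lexicographically by (smaller minimal original
  leaf index, larger minimal original leaf index); leaf ordering places
  the child with the smaller minimal original index on the left. Both
  rules exist purely so that identical inputs give byte-identical
  output.
- Height cuts use strict inequality (merges with height `< h` are
  applied), so `h = 0` cleanly returns singletons.
- Column-insertion ties (equal support) resolve toward the smallest
  column index, then the earliest position; candidate support is
  counted directly on the two affected adjacencies of each insertion,
  which agrees with re-scoring the whole extended order.
- The synthetic generator seeds R's RNG from `rng_seed` and restores
  the caller's RNG state, so generation is reproducible and
  side-effect-free.

## What the synthetic generator emulates

`generate_matrix()` plants one or more blocks in i.i.d. Gaussian
background noise of standard deviation `noise_sd`: block cell
$(i, j_k) = \mathrm{base} + k \cdot \mathrm{step} + \varepsilon$, with
$k$ the column's 1-based rank in the planted order. With the default
`base_level = 0` the block's lowest column sits one step above the
background level — an up-regulated module over a log-ratio background
centred at zero. Planted rows are disjoint across blocks; a planted
row's remaining columns are pure background, which exercises the
pipeline's ability *not* to over-grow columns.

This emulates exactly one difficulty of real data — additive noise on a
monotone consensus — and none of the others: no heavy-tailed or
correlated noise, no missing values, no overlapping modules, no
shift/scale heterogeneity between rows, no descending branches. Passing
the planted-recovery tests therefore shows the machinery is correct
under its own model, not that real transcriptomes will yield patterns
of comparable cleanliness.

### A structural limit of strict maximality

One property of the model is worth stating because it bounds every
planted-recovery benchmark. If all block levels sit above the
background, then *any* background column lies below the block's lowest
level in every block row (with probability essentially 1 for
`step/noise_sd = 10`), so a maximal strict pattern containing the block
must also contain one background-level column at its front — maximality
forbids emitting the bare block. Conversely, if the block's lowest
level sits *at* the background, that column is statistically
interchangeable with every background column and cannot be identified.
Either way, a maximal strict pattern differs from the planted block by
about one column, so cell-Jaccard recovery of a $20 \times 6$ block
plateaus near $120/140 \approx 0.86$ rather than 1. This is a property
of strict order-preserving maximality in Gaussian background, not an
implementation artifact; the recovered gene sets (what
`association_accuracy()` measures) are unaffected.

## Problem sizes used in the test suite

The suite exercises: 1,000 random vector pairs (lengths 2–50) against
the correlation definition; 100 random distance matrices ($n \le 50$)
against the naive agglomeration oracle; 100 matrices (50 random, 50
planted, up to $40 \times 10$) for the strict-pattern contract; 50
random matrices up to $15 \times 10$ for exhaustive maximality
re-checks; and 20 replicates of the planted $20 \times 6$ block in a
$100 \times 20$ matrix (`step = 1`, `noise_sd = 0.1`) for recovery.
These sizes keep the full suite under a minute while covering the
regimes where the algorithms branch.

## Known limitations

- `1 - r` is not a metric; only average linkage's reducibility, not any
  triangle inequality, is relied on.
- Growth is purely monotone: a locally admissible early insertion
  (e.g. a background column absorbed into a seed) is never revisited.
- Mining is seed-driven, not exhaustive: patterns whose rows are split
  across clusters at the chosen `k` can be missed; the miner
  deduplicates but does not merge overlapping patterns.
- The agglomeration is quadratic in genes per step; matrices beyond a
  few thousand genes need pre-filtering (e.g. by variance) before
  clustering.
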