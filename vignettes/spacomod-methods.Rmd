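---
title: "spacomod: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spacomod: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacomod)
```

This vignette is the package's own account of what it computes, which
assumptions those computations rest on, and why the open design choices
were made the way they were. Nothing stated here goes beyond what the test
suite and the acceptance script themselves compute.

## Annotation-average projection

SRT platforms with imaging chemistry measure a limited gene panel
(hundreds of genes); a paired scRNA-seq reference measures the
transcriptome but without coordinates. When both datasets are annotated in
the *same* cell-type taxonomy, a cheap transcriptome-wide spatial view is
obtained by label correspondence: compute, per annotation category $c$ and
gene $g$, the reference mean $\mu_{cg}$, then give every spatial cell with
label $c$ the expression row $\mu_{c\cdot}$.

The operative assumption is that annotations are fine-grained enough that
the category mean represents its members; with coarse annotations the
projection smooths away within-type heterogeneity, and downstream
"co-expression" within one category collapses to a constant. The
projection is exact in the following testable senses (both are asserted in
the suite at machine precision):

* averaging, projecting onto the same cells, and re-averaging returns the
  original averages exactly, and projecting twice changes nothing
  (idempotence);
* the *cluster-level* correlation of a dataset with its own averages is 1
  for every gene with between-category variance.

Two validation statistics are exposed: `cluster_level_correlation`
(Pearson r between per-category means, measured vs reference, over shared
categories) and `cell_level_spatial_correlation` (Pearson r across cells
between measured and projected values). The latter is bounded above by the
between-category share of variance, so it is systematically lower whenever
genes vary within a category — comparing the two quantifies exactly what
the projection discards.

Design choices: categories keep first-appearance order (locale-independent,
deterministic); spatial labels with no reference counterpart produce
all-zero rows, a recorded index list and a warning (an error under
`strict = TRUE`); values are used as stored — any log or depth
normalization is an explicit upstream step, because silently transforming
on read would make the projection irreproducible against the source file.
Averages are accumulated over cell blocks (`block_size`, default 5000), so
a large reference never needs to be resident next to the SRT matrix;
block-size invariance is tested.

## Cell selection

Three selection modes produce the same `CellSelection` object: all cells
with an annotation label; a flood-fill; or an explicit, order-preserving,
de-duplicated index list (the headless counterpart of lassoing an
embedding — the embedding itself is out of scope, we consume indices).

The flood-fill selects transcriptomically similar cells around a seed: a
kNN graph is built on expression rows (Euclidean by default; cosine and
correlation distances optional), and a breadth-first traversal expands the
frontier `steps` times along *directed out-edges* — each cell floods to its
own k nearest neighbours. The directed reading is well-defined without any
symmetrization convention and matches the "walk through the
high-dimensional neighbourhood" semantics of interactive tools; graph `k`
plays the role of the "flood nodes" parameter, the BFS depth the "flood
steps", with 10/10 as the conventional defaults. BFS visit order is
recorded so downstream output is deterministic.

The kNN graph is computed by blocked exact brute force at every size
(memory-bounded; no approximate mode). The reason is determinism: the
package contracts that neighbour lists are sorted by ascending distance
with ties broken by the lower cell index, which off-the-shelf kd-tree
implementations do not guarantee. BFS results are verified against an
independent linear-algebra reachability oracle (powers of $I + A$ applied
to the seed indicator) on random graphs, and monotonicity in `steps` is
asserted.

## Gene filters

All three filters score every gene *within the selected cells* and retain
the top `n_keep`, with ties broken lexicographically by symbol so the
resulting table is a total order (re-runs are byte-identical).

**Differential.** mean(selection) − mean(dataset), signed, descending: the
filter deliberately targets genes *high* in the selection, which is the
cell-type-marker reading; an absolute-value variant would also surface
depleted genes, but depletion is the complement selection's enrichment.

**Moran's I.** With spatial weights $w_{ij}$ built from the selected
cells' coordinates,

$$I = \frac{N}{W}\,
  \frac{\sum_{i}\sum_{j} w_{ij}(x_i-\bar x)(x_j-\bar x)}
       {\sum_i (x_i-\bar x)^2},
\qquad E(I) = \frac{-1}{N-1},$$

where $N$ is the number of selected cells and $W = \sum_{ij} w_{ij}$. The
statistic is evaluated exactly in vectorized form and is tested to agree
with a naive $O(N^2)$ double-sum evaluation within $10^{-10}$ on random
instances. Genes are ranked by |Z| with
$Z = (I - E(I))/\sqrt{\mathrm{Var}(I)}$ under the normality assumption:

$$\mathrm{Var}(I) = \frac{N^2 S_1 - N S_2 + 3W^2}{W^2 (N^2-1)} - E(I)^2,
\quad S_1 = \tfrac12\sum_{ij}(w_{ij}+w_{ji})^2,
\quad S_2 = \sum_i \Bigl(\sum_j w_{ij} + \sum_j w_{ji}\Bigr)^2.$$

The normality form was chosen because it is the standard closed form and
is checkable: the suite verifies that the permutation null of $I$ centers
on $-1/(N-1)$ within Monte-Carlo error, and that on spatially random genes
the |Z| > 1.96 flag rate sits at 5% ± 2% (measured 3–6% across seeds at
N = 100 cells, 500 genes). For pathological tiny-$N$ dense-weight
configurations the closed form can go negative; the sd is then `NaN` and
the Z-score undefined rather than silently wrong.

**Weights.** Only Euclidean distance underlies the weight matrix; its
aggregation is a declared default, not an inference: binary kNN with
k = 15 (cost bounded in the selection size, standard practice in
spatial-omics autocorrelation), with an inverse-distance-within-cutoff
scheme as the alternative. kNN weights are intentionally *not*
row-standardized — the statistic above already carries the $N/W$
prefactor — and are generally asymmetric; both properties are tested.
Coincident points under inverse distance are an error directing the user
to the kNN scheme. The scheme and its parameters are recorded in the score
table's provenance attributes.

**Axis correlation.** Pearson r between expression and one coordinate
axis, ranked by |r| so that gradients of both directions survive to
clustering — this is what lets a 2-module clustering split ascending from
descending gradients rather than having the filter discard one sign.

Genes whose statistic is undefined (zero variance within the selection)
are excluded from the ranking entirely rather than scored 0; otherwise a
plateau of constant housekeeping genes could displace informative genes at
the retention boundary. `n_keep` larger than the number of finite-score
genes retains all of them with a warning.

## Gene modules

Retained genes are clustered on the pairwise correlation distance
$d = 1 - r$ (0 identical shape, 1 uncorrelated, 2 anti-correlated) by
agglomerative hierarchical clustering, cut to exactly `k` flat modules.
Average linkage (UPGMA) is the default: it is the conventional partner of
correlation distances and, unlike complete linkage, does not let a single
outlying pair dictate a merge; complete linkage is available. Pearson
already centers and scales per gene, so no re-standardization is applied,
and module assignments are invariant to positive per-gene affine
rescaling (tested). `k` is a required user parameter — with exploration
data there is no defensible automatic choice, and the honest interface is
to expose it.

Module ids are relabelled deterministically (descending size, ties by the
lexicographically first member gene), so identical inputs give identical
outputs with no arbitrary color-assignment ambiguity. Per-module mean maps
are the arithmetic mean over member genes per selected cell; the
normalized variant is min–max scaled over the selection, with a constant
map defined as all-zero. Planted-module recovery on two anticorrelated
pattern blocks is exact (ARI = 1) up to noise sd of 0.1 of the signal
amplitude, and the flat cut at k = 2 is verified against brute-force
enumeration of all 2-partitions on a 6-gene fixture.

## GO enrichment

The offline engine tests each term by the one-sided hypergeometric tail:
with a background universe of size $N_b$, $K$ term genes in the universe,
and $n$ query genes, $p = P(X \ge k_{\text{obs}})$, Bonferroni-adjusted by
the number of terms tested, $\min(1, m\,p)$. P-values are exact against an
enumeration oracle (≤ 1e−12), monotone in the overlap, and the adjustment
is verified by construction. For panel-limited SRT queries the measured
panel is the background — over-representation is relative to what was
assayable, not the genome. Term tables load from two-column TSV or GMT.

The g:Profiler client sends the Bonferroni method flag and a custom
background when one is set; ToppGene accepts neither custom backgrounds
nor organisms, so such queries are rejected at construction time, before
any network traffic, and ToppGene is intended for transcriptome-wide
(projected) queries only. Request builders are pure functions and are
unit-tested; transport (httr, 30 s timeout, 3 attempts, exponential
backoff) raises a dedicated error class distinguishing a failed call from
a valid empty result. No test performs network I/O.

## Synthetic data

The generator emulates the structures the analysis is meant to find: an
integer grid (default 10 × 10 × 5 = 500 cells) jittered by U(−0.3, 0.3) —
the jitter exists solely to avoid degenerate distance ties in kNN and
weight construction; an annotation mosaic of contiguous slabs along the
second axis (deliberately orthogonal to the default gradient axis, so
markers and gradients stay unconfounded); and four gene classes: axis
gradients $a\,t$ and $a\,(1-t)$ in normalized coordinate $t$, Gaussian
hotspots $a\exp(-d^2/2r^2)$, annotation markers
$a\,\mathbf 1[\text{label}]$, and structureless baseline genes. Noise is
Gaussian truncated at zero (expression is non-negative); amplitude 5 and
noise sd $0.05a$ by default. The pseudo-scRNA companion carries a superset
panel (160 vs 120 genes by default) with cells drawn per annotation region
at virtual in-region locations, sharing the taxonomy.

What it does *not* emulate: count-distribution realism (negative binomial
sampling, depth variation), segmentation spillover between neighbouring
cells, anisotropic tissue geometry, or batch structure. Passing tests
therefore demonstrate the statistics and the plumbing are correct — that
gradients of known direction are ranked and separated, that null genes are
flagged at the nominal rate — not that any particular biological dataset
will behave as cleanly.

## Numerical and scale choices

* Expression is used as stored; `log1p` is an explicit option, never
  implicit.
* Undefined statistics are `NA` sentinels, excluded from ranking — never 0.
* All tie-breaks (kNN neighbours, score ranking, module relabeling) are by
  index or symbol, making every output a pure function of input + config +
  seed; pipeline reruns are byte-identical and this is asserted.
* Tables serialize floats with 15 significant digits so CSV round-trips
  reproduce values.
* Test and acceptance problem sizes — 500-cell grids, 100–200-cell random
  instances, 500-gene null panels, 1000 permutations — were chosen as the
  smallest sizes at which the Monte-Carlo checks have adequate power;
  the whole suite runs in well under a minute.

## Known limitations

* Projection fidelity is bounded by annotation granularity; there is no
  probabilistic label transfer or imputation, by design.
* The Moran Z-score uses the normality approximation rather than a
  per-gene permutation p-value; the permutation null is used to *validate*
  the approximation, and ranking (the actual use) depends only weakly on
  the tail shape.
* The filter ranks and truncates; it performs no multiple-testing control
  across genes — the |Z| > 1.96 threshold is a guideline for interpreting
  the bar of retained genes, not an error-rate guarantee.
* Modules are a hard partition; overlapping or soft co-expression
  structure is not represented.
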