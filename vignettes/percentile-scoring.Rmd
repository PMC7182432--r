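---
title: "Percentile scoring of gene modules in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile scoring of gene modules in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgps)
```

## The problem

Droplet scRNA-seq assigns each cell a sparse vector of UMI counts. Many
questions about such data are not about single genes but about programs:
is this cell cycling, does this cluster run a mucin-secretion program, do
cells of a hybrid state carry elevated expression of a disease-associated
gene list? A per-cell *module score* answers these by collapsing a gene
set into one number per cell that can be plotted, compared between
clusters, and tested between genotypes.

The score implemented here is a percentile statistic. For each gene $i$,
every cell is ranked on its log-normalized expression against all cells
in the dataset; equal values receive the lowest (minimum) rank; ranks are
rescaled to $[0,1]$. For a module of $m$ genes the score of a cell is

$$\mathrm{score} = \frac{1}{m}\sum_{i=1}^{m}\mathrm{PercentRank}_i,$$

so a score of $p$ says the module's mean expression sits at the $p$-th
percentile for that cell. Because ranks are invariant under any strictly
increasing per-gene transform, the statistic does not depend on the log
base, the pseudocount, or the scaling constant — only on the ordering of
cells within each gene.

## The one consequential interpretation

"Rescaled to $[0,1]$" admits two common conventions, $(r-1)/(N-1)$ and
$r/N$. This package fixes

$$\mathrm{PercentRank}(g,c) = \frac{\operatorname{rank}_{\min}(g,c) - 1}{N-1},
\qquad
\operatorname{rank}_{\min}(g,c) = 1 + \#\{c' : x_g(c') < x_g(c)\},$$

which maps the lowest value to exactly 0 and a unique maximum to exactly
1, and is the standard percent-rank definition in the data-manipulation
ecosystem. Consequences worth knowing:

* a gene constant across cells scores 0 in every cell (all cells tie at
  the lowest rank), so uninformative genes dilute a module toward 0
  rather than toward 0.5;
* a tie-free gene has mean percent rank exactly 0.5 across cells;
* with UMI data the minimum of nearly every gene is 0, so all dropout
  cells score 0 for that gene. Ranks are therefore computed over the
  stored nonzeros only — zeros are known to take rank 1 — and the rank
  matrix stays as sparse as the input.

The test suite pins this convention bit-for-bit against a brute-force
double-loop oracle, so any future change of scaling is loudly visible.

## Input layer and missing genes

Scoring operates on the log-normalized layer,
$\ln(1 + c_{gc} \cdot S / \mathrm{total}_c)$ with $S = 10^4$ by default
(natural log). The scale factor and log base are configurable; by the
monotone-invariance property they cannot change any score as long as one
normalization is applied consistently, so the default is a convention,
not a claim. Scoring raw counts is refused unless explicitly overridden,
because unequal library sizes change within-gene orderings.

Module genes absent from the matrix are dropped and $m$ reduced, with a
warning and a record in the run log — missing features usually reflect
annotation mismatch rather than absence of expression. The alternative
(count absent genes as percent rank 0, keeping $m$ at the full module
size) is available behind `missing_as_zero = TRUE`; it penalizes every
cell equally and so shifts but never reorders scores within a set.

## Group comparisons

Score and marker comparisons use the Wilcoxon rank-sum test, two-sided
by default. For combined samples of at most 16 tie-free observations the
p-value comes from the exact distribution; above that (or under ties) a
tie-corrected normal approximation with continuity correction is used.
The threshold of 16 is where the two routes agree closely: enumerating
all achievable values of the U statistic, the approximation is within
0.03 of the exact p for all group sizes of five or more, while below
that the approximation can err by ~0.1 — which is precisely why the
exact path exists, and why the regression test of approximation quality
covers the handover zone rather than the tiny sizes the exact path
always handles. A fully tied comparison gets p = 1 by symmetry rather
than NaN.

Effect sizes follow the scale of the unit compared: for module scores,
the difference of group means (scores already live on a common $[0,1]$
scale); for single-gene expression, the log-fold-change of group mean
de-logged expression, $\ln\big((\overline{e^{x_a}-1}+1) /
(\overline{e^{x_b}-1}+1)\big)$, the convention of the mainstream
single-cell toolkits. Multiple testing uses Benjamini–Hochberg, applied
within each gene set across contrasts (score comparisons) or within each
cluster across genes (marker scans). BH is a package decision — the
procedure behind published "adjusted p-values" is often unstated — and
is deliberately the least surprising choice.

The marker scan pre-filters genes expressed in under 10% of both groups
or with |logFC| < 0.25, the standard desk-scale defaults; both filters
can be set to 0 to test everything.

## The synthetic generator

Real atlases come with alignment pipelines and deposited archives; the
package instead ships a generator that reproduces the *structure* the
score is meant to detect, so the full pipeline is testable offline.
Counts are negative binomial:

$$c_{gc} \sim \mathrm{NB}\big(\mu_g \, d_c \, \mathrm{FC}(g, \mathrm{cluster}(c), \mathrm{genotype}(c)),\ \theta\big)$$

with lognormal gene baselines $\mu_g$, lognormal cell depth factors
$d_c$, a shared dispersion $\theta$, and planted modules whose genes are
multiplied by a fold change in one target cluster (optionally overridden
for knockout cells, so wild-type-vs-mutant contrasts have ground truth).
Defaults — 1,000 genes, 3 clusters of 300 cells, baseline
$\mathrm{LogNormal}(-1.5, 1)$, $\theta = 2$, depth sigma 0.3, one
50-gene module at fold change 4 — give cells of roughly 400 UMIs with
~25% nonzero entries, a deliberately modest but realistic droplet
profile, and are also the reference condition for the recovery
experiments. All draws derive from one seed in a fixed order, so a
configuration reproduces its counts bit-exactly.

What the generator does *not* emulate: doublets, ambient RNA, batch
effects, per-gene dispersion, zero inflation beyond NB sparsity, and
continuous trajectories. Passing recovery tests therefore show that the
statistic detects planted mean-shift co-regulation under overdispersed
sparse counts of varying depth — not that it is robust to artifacts the
generator never produces.

## Validation design and problem sizes

Three layers of evidence, all computed at run time:

1. **Exactness.** The vectorized sparse implementation is compared
   bit-for-bit against a literal double-loop oracle of the rank
   definition on over a hundred random fixtures with engineered tie
   blocks (up to 100 genes × 200 cells), and the exact rank-sum path
   against exhaustive permutation enumeration for all group sizes up to
   a combined 10.
2. **Recovery.** At the reference condition (fold change 4, $m = 50$,
   3 × 300 cells) the target cluster has the highest mean score and the
   target-vs-rest contrast is significant at BH-adjusted p < 0.01.
3. **Calibration.** With the fold change set to 1 (no signal), across
   200 replicate simulations of 500 genes × 300 cells the target
   contrast rejects at ~5% as it should, and the mean absolute score
   difference between clusters stays within Monte-Carlo noise of 0.

These sizes keep each layer in the seconds-to-a-couple-of-minutes range
on a single core while leaving the statistics well-resolved; they are
the package's validation conditions, stated here so results are read
against them.

## Numerical and degenerate-input choices

* Duplicate gene identifiers on ingestion are collapsed by summation
  (one identifier must map to one row for identifier-driven scoring);
  the collapse preserves per-cell totals and is order-independent.
* Gene matching is exact and case-sensitive; a case-insensitive mode
  exists but is off by default.
* Per-gene z-scores of cluster means use the sample SD; genes with zero
  variance across clusters map to 0, not NaN, so summaries render.
* Cells with zero total counts are rejected by name rather than
  producing silent NaNs.
* Output ordering is deterministic everywhere (sets in collection
  order, cells in matrix order, contrasts in level order), and pipeline
  files are written atomically, so reruns are byte-stable.

## Limitations

The score is non-competitive: it asks whether a module's genes rank high
in a cell, not whether they rank higher than a matched background set,
so global cell covariates (total detected genes, stress response) can
move scores for many modules at once. Percent ranks are computed against
whatever cell population is passed in — scores are relative to that
dataset, and subsetting cells changes them by design; callers who want
per-stage or per-compartment percentiles should subset first. For
competitive or running-sum enrichment, use a GSEA-family method instead.
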