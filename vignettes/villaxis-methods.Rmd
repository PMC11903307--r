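---
title: "Anatomical coordinates, IMAPs and perturbation decoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical coordinates, IMAPs and perturbation decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villaxis)
```

`villaxis` analyses imaging-based spatial transcriptomics of the small
intestine by giving every cell a position in the tissue's own coordinate
system and then asking how expression, neighbourhoods and perturbation
outcomes vary along those coordinates. This vignette explains the models
and the design decisions behind each stage; the quantitative claims it
makes are exactly those computed by the test suite and
`scripts/acceptance.R`, nothing more.

## The coordinate model

The small intestine is a repeating structure: finger-like villi rising
from crypts, over a smooth-muscle muscularis. Three coordinates capture a
cell's anatomical position.

**Longitudinal axis.** The base of the basal membrane is annotated as a
polyline running along the gut. Each cell is orthogonally projected onto
the nearest polyline segment and reported as the arc-length fraction of
that nearest point (0 = start, 1 = end). The projection is exact segment
geometry, not a sampled search; the test suite checks it against a dense
(10^4-point) sampling oracle to within 10^-3.

**Crypt–villus axis.** The raw value is the Euclidean distance from the
cell to the basal-membrane polyline, signed positive on the villus side
and negative on the muscularis side (the sign comes from the cross
product with the directed segment, so a left-to-right annotation puts
villi above). Because villi differ in height, raw distances are z-scored
*within each segmented villus* — villus masks are an input, not something
this package recomputes from images. We use the population standard
deviation (divide by n), mapping zero-variance or singleton villi to 0;
the choice of population vs sample denominator is a convention the
upstream method leaves open, fixed here so that a three-cell villus with
raw distances {1, 2, 3} scores exactly {−1.2247, 0, +1.2247}. A
per-sample min–max rescale of the z-scores to [0, 1] is carried alongside
for display and gating, matching the colouring convention of published
maps.

**Predicted crypt–villus axis.** Sections with poor morphology get axis
values predicted from transcriptional neighbourhoods instead: for each
cell the counts of its 10 nearest epithelial and stromal neighbours are
summed (immune populations are excluded from the neighbour pool because
their composition shifts with infection state), the neighbourhood matrix
is decomposed by seeded non-negative matrix factorization into 15
per-cell factor loadings, and a supervised regressor maps loadings to
axis values learned on cells whose geometric axis is trustworthy.
Predictions are then smoothed by averaging over each cell's 150 spatially
nearest cells (the cell itself included, so a smoothing neighbourhood of
1 is the identity). The regressor is pluggable; the default is a k-NN
regressor (k = 25) on the factor space, chosen because it is
deterministic, has no tuning surface beyond k, and the downstream
contract — factors in, smoothed axis out, held-out error reported — does
not depend on the regressor family. On synthetic tissue, training on one
sample and scoring another yields Spearman ≈ 0.99 against ground truth,
comfortably above the 0.8 the package commits to in its tests.

**Epithelial axis.** The mean distance to the 5 nearest epithelial cells
divided by the mean distance to the 5 nearest cells of any type, self
excluded in both queries. With equal neighbourhood sizes the ratio is ≥ 1
(the any-type set minimizes the mean), with 1 meaning the local
neighbourhood is entirely epithelial. Ratios are z-scored over the sample
and clipped at +3 z-units: the clip bound is a free parameter upstream
("an upper bound"), and +3 keeps the far tail — cells deep in the
muscularis — from dominating the transformed scale.

## IMAPs

An immune allocation map positions each cell at
(crypt–villus, T(epithelial)) where T is a biexponential transform
realized as `asinh(v / w)`. The transform family is named but not
parameterized upstream; `asinh` is the standard invertible member —
linear within ±w, logarithmic beyond — and the default width w = 0.5
z-units puts the epithelial boundary region (|z| ≲ 0.5) on the linear
part of the scale. Whether the IMAP x-coordinate should be the z-scored
or the display-rescaled crypt–villus value is likewise unspecified
upstream; both are available, with the display rescale the default since
gates are most naturally drawn in a fixed [0, 1] frame.

Density surfaces are weighted Gaussian product-kernel KDEs. Weights
(gene counts, or *squared* signature scores — squaring is applied only to
signature weights, where it counteracts the bias of cell-density-dominated
maps) are normalized to sum to 1, so equal weights reproduce the
unweighted estimate bit-for-bit. The bandwidth default is Scott's rule
with the effective sample size `1/Σw²` in place of n, computed on the
weighted cloud. The evaluation grid extends 3 bandwidths plus a 10%
margin beyond the data, which keeps the grid integral of the density
within 1% of 1 at the default 128×128 resolution.

Gates are simple polygons, validated against self-intersection at load.
Membership is boundary-inclusive; overlapping gates resolve by
declaration order. Per-gate fractions are reported over
{gates ∪ none}, so they always sum to 1.

Signature scores are rank-based: genes are ranked per cell by descending
count (average ranks on ties), ranks are truncated at `r_max` (default
1500), and the score is `1 − (Σ ranks_sig − n(n+1)/2)/(n·r_max)`, floored
at 0. A cell whose signature genes occupy the top n ranks scores exactly
1; when every signature gene ranks beyond `r_max` the score reaches its
truncation floor `(n+1)/(2·r_max)` (≈ 0.001 at defaults) — effectively
but not identically zero, a property the tests assert exactly.

## Gradient screens and trends

The screen takes the cells of one population (e.g. antigen-specific CD8 T
cells), keeps genes detected in at least 5% of them (count > 0;
boundary inclusive), and computes each gene's Spearman rank correlation —
average ranks for ties — with each axis, with p-values from the
large-sample t approximation. Genes are classed positive/negative at
|ρ| > 0.05. That threshold is deliberately permissive — it exists to
contrast axes, not to control error — and at a few hundred cells the
null distribution of ρ is wide enough that a noticeable fraction of truly
flat genes crosses it; the package therefore validates the screen's
operating characteristics at n = 2,000, where planted log-linear slopes
of +1 are detected in 100% of 50 simulations while null-gene calls stay
within the 99% binomial band of a permutation null computed on the same
counts. Raw counts (not normalized expression) enter the correlation by
default: rank correlation against an axis is unaffected by monotone
per-gene scaling, and normalization is left as an option for populations
with strongly heterogeneous totals.

Trends along an axis come in two forms. The *convolved* trend sorts cells
by axis value and averages counts over a sliding window of fixed cell
count; at the edges the window shifts inward rather than shrinking, so a
window of 1 returns the raw sorted counts and a window of n the global
mean everywhere. The *additive-model* trend fits a GAM — a single
cubic-regression-spline smooth, penalty chosen by generalized
cross-validation — and evaluates it on a uniform grid, z-scaled so trends
of differently expressed genes are comparable; constant input degenerates
to an all-zero curve by convention. Because the spline's penalty null
space contains linear functions, an exactly linear signal is reproduced
to numerical precision, which the tests exploit as an oracle.

Spatial signatures are built by two-sided Wilcoxon rank-sum tests on
log-normalized counts between gated regions (exact p-values for small
tie-free samples, normal approximation otherwise), Benjamini–Hochberg
adjusted, ranked by the standardized statistic; the top 15 genes form a
region signature (top 8 for the TGFβ-program variant used in
proximity analyses).

## Proximity statistics

The substrate is an explicit spatial graph: symmetrized k-NN with k = 6
by default — the upstream analysis relies on a neighbourhood library's
internal default, and an explicit, reproducible graph is preferred here —
with Delaunay (degenerate layouts fall back to k-NN with a warning) and
fixed-radius variants. Interaction scores count graph edges per ordered
type pair (symmetric by construction), average across replicates over the
union of types, and are reported in two normalizations: max-normalized to
[0, 1], where the 0.1 display threshold corresponds to "10% of the
strongest connection", and row-normalized (rows sum to 1) for heat maps.

Nearest-type distances are Euclidean and self-excluded — a cell's
distance to its own type is the distance to the *other* nearest cell of
that type. Expression–distance correlations are Spearman, computed per
sample and averaged; the sign convention is that negative ρ means
expression is higher *near* the target type. Condition-level proximity
comparisons use the two-sample Kolmogorov–Smirnov statistic with the
conventional 0.08 cutoff: D ≤ 0.08 is reported "similar", above it
"different".

## Perturbation decoding

Each sgRNA in a pooled design is encoded by a pseudogene barcode carrying
7 or 8 hybridization sites for one landing gene chosen among the panel's
least-expressed members (Muc5ac, Neurog3, Fer1l6 in the default
three-guide design); landing genes must be unique across guides. Channel
counts are read directly from the cell-by-gene matrix; the tentative
guide is the strictly maximal channel with at least one count, ties are
labelled ambiguous rather than majority-assigned (collision handling is
not specified upstream; the strict rule is conservative and documented).

A cell is *called* perturbed only when four criteria hold simultaneously:
raw Cd8a+Cd8b1+Cd3e ≥ 3 (raw counts, not normalized — identity filtering
happens before any scaling), ≥ 1 barcode, membership in a configured CD8
T cell cluster set (cluster labels are inputs; clustering is out of
scope), and ≤ 1 Muc2 transcript. The Muc2 rule exists because the Fer1l6
channel shows low expression in goblet cells, so goblet transcript
bleed-over could otherwise masquerade as a perturbed T cell; the
synthetic generator reproduces exactly this failure mode as its
contamination scenario, and with it active the caller still achieves
precision 1 on synthetic truth. The caller is a pure function of its
five inputs, and the tests re-derive every call with an independent
brute-force evaluation of the four rules.

Perturbation differential expression uses Welch (unequal-variance)
two-sided t-tests — the upstream method says only "two-sample t-tests",
and Welch is the safer default — on log-normalized counts, BH-adjusted
within each pairwise guide comparison, with significance tiers at
0.05/0.01/0.001, plus a gate-stratified variant and a barcode-uniformity
diagnostic (Spearman ρ of barcode count against the crypt–villus axis,
expected ≈ 0 when detection is spatially unbiased).

## The synthetic tissue

The generator is the package's test bed, and its defaults define the
simulated study conditions: 10 villi of 400 µm × 120 µm over a 60-µm
muscularis band, 500 cells per villus unit (150 epithelial on the villus
outline, 250 lamina propria inside, 100 muscularis) for ≈ 5,000 cells per
section — the scale of one villus-rich region of a real section, chosen
so every stage runs in seconds. The tissue is laid out *flat* rather than
as a rolled spiral: all three axes are defined relative to the basal
membrane, which a flat layout captures without the registration
complexity of a roll; the longitudinal axis remains well defined. Cell
types follow fixed per-compartment frequencies (epithelium dominated by
enterocytes with goblet cells and progenitors; lamina propria a mix of
CD8/CD4 T cells, B cells, fibroblasts and dendritic cells; muscularis
mostly smooth muscle).

Counts follow `Poisson(exp(b0 + b_cv·cv + b_epi·epi + b_long·long))` per
gene, restricted to the gene's eligible cell types; a negative-binomial
option adds overdispersion for robustness checks. Slopes of ±0.5–1.2 on
the unit-scaled axes give rate ratios of e^0.5–e^1.2 across the villus —
the magnitude of the strong published gradients (granzymes, Tcf7,
enterocyte zonation genes) — and ten null genes have exactly zero slope
by construction. Nuclear counts are a Binomial(total, 0.5) draw.
Ground-truth axes are exact functions of placement (no noise), so
axis-recovery tests have a noiseless reference.

What the generator does *not* emulate: optical physics, probe chemistry,
segmentation errors (beyond the goblet bleed-over contamination),
cell-shape effects, and the count-depth heterogeneity of real platforms.
Passing tests therefore demonstrate that the algorithms are correct and
well calibrated under their stated model, not that real sections will
reach the same recovery numbers.

## Numerical conventions and degenerate inputs

* All k-NN queries exclude the query cell itself.
* Nearest-centroid ties in multi-nucleus splitting go to the
  lower-indexed centroid; QC thresholds are strict for removal (n < 8
  nuclear, n < 20 or n > 800 total), so boundary cells are kept.
* Bins are assigned to the cell whose mask contains the bin centre,
  which conserves totals and never double-counts.
* Zero-variance groups: per-villus z-scores become 0; constant genes
  screen as class "none" (undefined ρ); constant trend input z-scales to
  an all-zero curve; genes constant across both DE groups get p = 1.
* Duplicate coordinates floor the epithelial-axis denominator at 1e-9
  with a warning.
* Determinism: every stochastic step (generator, NMF initialization,
  holdout splits) takes an explicit seed, and running the pipeline twice
  with one seed produces byte-identical outputs.

## Problem sizes used by the checks

The test suite and acceptance script run on: one default 5,000-cell
section (axis recovery, decoding), a two-section pair (cross-sample
prediction), 50 replicate simulations at n = 2,000 (screen operating
characteristics), and 30–200-point constructed layouts for the exact
oracles. These sizes were chosen as the smallest at which the measured
properties are stable, keeping the full suite within a few minutes on a
single CPU.

## Known limitations

* Villus segmentation, cell segmentation and cell typing are inputs;
  errors there propagate into every axis.
* The longitudinal axis assumes the basal-membrane annotation is ordered
  along the gut; for a rolled section, the upstream restriction of
  candidate points to the inward side of the roll is not implemented
  (flat geometry makes it moot here) and would be needed for real
  Swiss-roll sections.
* The interaction score is a raw contact count, not a
  composition-corrected enrichment; comparing tissues with very
  different type abundances should use the row-normalized variant with
  that caveat in mind.
* The ρ > 0.05 screen threshold is a highlighting device; at small n it
  admits a predictable fraction of null genes (see the operating
  characteristics above), and any inferential use should rely on the
  reported p-values instead.
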