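# villaxis

Anatomical axes, immune allocation maps and in situ perturbation decoding
for spatial transcriptomics of the small intestine.

## The problem

Imaging-based spatial transcriptomics (10x Xenium, Vizgen MERSCOPE)
resolves hundreds of transcripts in single cells across whole sections of
the small intestine. The tissue is built from a repeating unit — the
villus with its crypt and the muscularis beneath — and immune cells such
as tissue-resident memory CD8 T (T_RM) cells occupy characteristic
positions within that unit: differentiated effector-like cells near the
villus top and epithelium, progenitor-like cells near the crypt.
Quantifying that organization requires putting every cell on a common
anatomical coordinate system and asking how expression, cell contacts and
perturbation outcomes vary along it.

`villaxis` provides that computational layer:

* **Three anatomical axes per cell.** The *longitudinal* axis is the
  arc-length fraction of the cell's nearest point on the basal-membrane
  polyline. The *crypt–villus* axis is the (signed) distance to the basal
  membrane, z-scored among cells of the same segmented villus, so
  villi of different heights become comparable; for sections with
  unusable geometry the axis is predicted from a non-negative matrix
  factorization (15 factors) of summed transcript counts over each cell's
  10 nearest epithelial/stromal neighbours, smoothed over 150 spatial
  neighbours. The *epithelial* axis is
  `mean(dist to 5 nearest epithelial cells) / mean(dist to 5 nearest cells)`,
  z-scored and clipped at +3 (the ratio is ≥ 1 by construction).
* **IMAPs (immune allocation maps).** Cells are placed at
  (crypt–villus, `asinh(epithelial/w)`) and summarized by a weighted
  Gaussian kernel density — weights are gene counts or squared signature
  scores — with manually drawn polygon gates (villus top, crypt,
  muscularis) and per-gate statistics.
* **Gradient screens.** Per-gene Spearman rank correlation with each
  axis over cells expressing the gene in ≥ 5% of the population, classed
  positive/negative at |ρ| > 0.05; trends as moving-window convolutions
  or penalized-spline (GAM) fits, z-scaled for comparison.
* **Proximity statistics.** k-NN/Delaunay/radius spatial graphs; the
  cell-type × cell-type interaction "connectome" (replicate-averaged, with
  a 0.1 max-normalized display threshold and a row-normalized heat-map
  variant); nearest-cell-type distances; expression–distance rank
  correlations; two-sample Kolmogorov–Smirnov comparison of proximity
  distributions with a 0.08 similarity cutoff.
* **Pooled-perturbation decoding.** sgRNAs are optically encoded by
  pseudogene barcodes landing on low-expression panel genes (Muc5ac,
  Neurog3, Fer1l6; 7–8 hybridization sites). A cell is called perturbed
  only if the raw Cd8a+Cd8b1+Cd3e marker sum is ≥ 3, at least one barcode
  is detected, the cell sits in a CD8 T cell cluster, and it has ≤ 1 Muc2
  transcript (guarding against goblet-cell bleed-over). Downstream:
  pairwise Welch t-tests on log-normalized expression with
  Benjamini–Hochberg correction, gate-stratified variants, and a
  barcode-uniformity diagnostic.
* **A synthetic tissue generator** (`synth_config()`, `generate_sample()`)
  that lays out villi, crypts and muscularis with epithelial, immune and
  stromal cells, draws counts from per-gene log-linear models
  `Poisson(exp(b0 + b_cv·cv + b_epi·epi + b_long·long))`, injects barcoded
  perturbations with an optional known-direction positional shift, and
  records exact ground truth — so the whole pipeline is testable without
  any external download.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R   # three synthetic sections + ground truth
Rscript analysis/02_axes.R       # QC and the three axes
Rscript analysis/03_imap.R       # IMAPs, gates, weighted densities
Rscript analysis/04_gradients.R  # gradient screen and trends
Rscript analysis/05_proximity.R  # connectome and distance statistics
Rscript analysis/06_perturb.R    # barcode decoding and perturbation DE
```

writes tables under `results/` and prints, among others:

```
A: removed 199 cells (78 low-nuclear, 161 low-total, 0 high-total)
  crypt-villus recovery (Spearman vs truth): 0.999
predicted axis, trained on A scored on B: Spearman 0.992
```

— the geometric crypt–villus axis recovers the generator's true
normalized villus height almost perfectly, and the neighborhood-NMF
predictor transfers across samples.

```
Gzmb-weighted density peaks at crypt-villus 0.79 (mass 1.000)
Tcf7-weighted density peaks at crypt-villus 0.24 (mass 1.000)
```

— effector-weighted IMAP density sits in the upper villus, progenitor
density near the crypt, reproducing the planted two-state geography.

```
sgCd19 gate occupancy:  top 23%, crypt 50%, muscularis 27%
sgCxcr3 gate occupancy: top 100%, crypt 0%, muscularis 0%
barcode-count uniformity along crypt-villus axis: rho = -0.010
```

— the decoded sgCxcr3 population (planted with an upward positional
shift) is enriched in the villus-top gate while the control guides match
the unperturbed distribution; calls against ground truth are
precision 1.000, and barcode detection is spatially unbiased.

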