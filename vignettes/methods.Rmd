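---
title: "Methods: two-level conservation prioritization on nested grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level conservation prioritization on nested grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`prioritygrid` implements a hierarchical (two-resolution) systematic
conservation planning workflow for presence-only species data on regular
lon/lat grids. The workflow has five stages, each usable on its own:

1. **Predictor preparation.** Fine-resolution environmental layers are
   aggregated onto a nested coarse grid (mean for continuous layers, modal
   class for the single categorical land-cover layer) and screened for
   collinearity by variance-inflation factor, VIF\(_j = 1/(1-R^2_j)\), where
   \(R^2_j\) is from OLS of layer \(j\) on all other retained continuous
   layers. Layers are dropped one at a time, largest VIF first, until all
   VIFs are below 5.
2. **Ensemble habitat-suitability modelling.** Per species, presences are the
   grid cells holding occurrence records; the background is a uniform
   without-replacement sample of non-presence cells (500 at the coarse level,
   200 at the fine level by default). Each learner in the ensemble is scored
   by mean held-out AUC over stratified cross-validation folds and refitted
   on all data; the consensus suitability is the AUC-weighted mean over
   learners with AUC > 0.7 (weights are the raw AUC values).
3. **Binary range construction.** The consensus layer is thresholded by the
   largest of four candidate thresholds — largest threshold with sensitivity
   ≥ 0.9 (minimal predicted area), maximum accuracy, maximum Cohen's kappa,
   maximum TSS — which minimizes commission error. Record cells are presences
   regardless of the model. Suitable areas isolated from all record-bearing
   patches by an unsuitable barrier wider than the mean nearest-neighbour
   distance between records (\(\bar d\)) are removed (8-connected components;
   minimum cell-centre distance). Species with a single record keep exactly
   their occupied cell.
4. **Priority indices and gap analysis.** Per cell: species richness (range
   count); *conservation value* — irreplaceability with no cell protected;
   *complementarity* — irreplaceability of unprotected cells crediting
   reserve contributions toward targets. Irreplaceability of cell \(x\) is
   \[
     \mathrm{Irr}(x) \;=\; \frac{\#\{C \ni x : C \text{ meets all targets},\,
       C\setminus\{x\}\text{ fails}\}}{\#\{C : C \text{ meets all targets}\}},
   \]
   with combinations \(C\) over all subset sizes of the available cells.
   Reserve polygons become protected cells through the coverage threshold
   that best matches total reserve area; species targets scale from 100% of
   range cells (smallest range) to 5% (largest), linear in log range size,
   rounded to the nearest integer cell count; species are classed *met*,
   *partial gap*, or *total gap*.
5. **Cross-scale congruence.** Pearson correlations between fine-level and
   coarse-level indices are tested against a one-sided Monte-Carlo
   permutation null (default 30 000 permutations,
   \(p = (1+\#\{r_{\mathrm{exp}} \ge r_{\mathrm{obs}}\})/(1+n)\),
   significance at \(p \le 0.05\)); species protection percentages are
   arcsine-square-root transformed first. Top-1% priority envelopes are
   extracted per index at both scales and fine-envelope nestedness within
   the coarse envelope is reported.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| pseudo-absences | 500 coarse / 200 fine | cells | background sample representing available conditions; scaled down automatically only if the grid is small (a validation error otherwise) |
| CV folds | 10 | — | effective folds are `min(folds, n_presence, n_absence)` so a stratified held-out fold always contains both classes |
| AUC cutoff | 0.7 | — | learners at or below it get consensus weight 0 |
| sensitivity floor | 0.9 | proportion | minimal-predicted-area criterion (a) |
| VIF threshold | 5 | — | collinearity screen stop rule |
| target percentages | 100 / 5 | % of range | anchors of the log-linear target interpolation |
| envelope fraction | 0.01 | proportion | "best 1%" priority envelope |
| permutations | 30 000 | — | Monte-Carlo null for correlation tests |
| `exact_limit` | 20 | cells | switch from exact enumeration (≤ 2^20 subsets) to the sampled estimator |
| `n_samples` | 10 000 | subsets | sampled-estimator draws (minimum 1000) |

# The synthetic-data generator

`make_world()` builds the world every downstream stage is tested against:
spatially autocorrelated continuous predictors (Gaussian-blurred white
noise — distribution models need spatial structure to beat chance), one
categorical land-cover layer (quartile classes of another smooth field),
species whose true suitability is a logistic function of a random linear
combination of predictors, true ranges as upper suitability quantiles
(species-specific, drawn in [0.70, 0.90]), presence-only records sampled
uniformly from true-range cells with sub-cell jitter, and axis-aligned
cell-aligned rectangular reserves whose summed area matches the requested
fraction of the extent within one fine cell's area (cell alignment makes
area accounting exact in tests).

Default record counts (1, 12, 25, 50, 80, 160 across six species) mirror the
skewed empirical distribution of tortoise locality data — from a
single-record species through a few hundred records — without reproducing
any particular dataset. The single-record species exercises the
occupied-cell-only rule end to end.

What the generator does **not** emulate: sampling bias (records are uniform
in the range, real records cluster near roads and collections), spatially
autocorrelated observation error, irregular coastlines/masked cells,
non-rectangular reserves, and projection distortion (degrees are treated as
planar). A green recovery test therefore establishes that the machinery
recovers *this* stated world, not that any field dataset would behave as
well.

# Numerical choices and tie-breaks

- **Cell convention.** Row-major ids, row 1 at the north edge; cell boxes
  are half-open (left/top edges closed on the west/north side of each cell),
  so boundary points belong to exactly one cell.
- **Aggregation ties.** Modal land-cover class ties resolve to the smallest
  class label; VIF ties to the first layer name in sort order. Both are
  purely for determinism.
- **Threshold search** runs over the observed unique scores; argmax ties take
  the larger threshold (commission minimization). If the chosen threshold
  classifies perfectly, it is moved to the midpoint of the separating gap —
  the documented degenerate-case convention.
- **Barrier clipping** uses 8-connectivity and a single retention pass
  (recordless patches are compared against record-bearing patches only);
  a fixpoint variant (`chain = TRUE`) is exposed because transitive retention
  is a defensible alternative reading.
- \(\bar d\) is the mean over records of the distance to the nearest other
  record. Averaging over mutually-closest pairs instead is a possible
  alternative reading; nearest-neighbour means are implemented.
- **Irreplaceability estimator.** The sampled estimator draws subsets by
  independent Bernoulli(0.5) inclusion: conditional on meeting the targets,
  sampled subsets are uniform over all meeting combinations, so the
  critical/meeting ratio is a conditionally binomial, unbiased estimate of
  the exact value, with SE \(\sqrt{p(1-p)/m}\) (floored at \(1/2m\)) for
  \(m\) meeting subsets. A closed-form "predicted irreplaceability"
  approximation in planning software is deliberately *not* re-implemented;
  the definitional ratio is computed exactly (enumeration) or by sampling.
  If targets make meeting subsets astronomically rare (e.g. a species whose
  whole large range is its target), the estimator stops with an explicit
  error rather than returning a silent zero.
- **Inclusion probabilities other than 0.5** change the weighting of subset
  sizes and therefore the measured quantity; the option exists but the
  default is the definitional, testable convention.
- **Targets** use natural log in the interpolation (the base cancels in the
  two-point form) and nearest-integer rounding. Published target tables of
  this kind are not reproducible in full under any single rounding
  convention; nearest-integer reproduces the robust subset and the
  remaining one-cell deviations are accepted, not chased.
- **Percent target met** uses integer protected-cell counts. Tables computed
  from fractional polygon coverage differ in decimals; the integer-count
  convention is the implemented and documented one.
- **Coverage threshold** compares strictly (`coverage > threshold`), matching
  the convention that a cell is protected when park coverage *exceeds* the
  threshold.

# Design decisions taken where the design was open

- The ensemble is a *learner contract* (fit/predict pairs mapping predictor
  vectors to [0,1] scores) rather than a binding to five named algorithms;
  a linear-logistic learner, a boosted-tree learner and a randomized
  tree-ensemble learner ship in-package (no tree package is available at
  run time, so a small shared regression-tree engine is included). The
  consensus, thresholding and clipping logic — the substance here — is
  learner-agnostic.
- Cross-validation is stratified by class and seeded; with very few records,
  folds shrink to keep both classes in every held-out set.
- Fine-versus-coarse per-cell pairing defaults to *replicate* mode (each
  fine cell against its parent's value); *aggregate* mode (fine means per
  coarse cell) is exposed.
- Per-species cross-scale comparisons pair only species present at both
  levels.
- One master seed fans out to per-stage, per-species seeds through a
  deterministic counter scheme, so reruns are bit-identical and per-species
  work is order-independent.

# Known limitations

- Planar degrees: no great-circle distances, no projections.
- Irreplaceability is exact only up to `exact_limit` cells; beyond that the
  sampled estimator carries Monte-Carlo error (reported as SE).
- The priority-envelope threshold scan cannot select *all* cells of a layer,
  and heavily tied integer layers (coarse richness) can realize envelope
  fractions far from 1%, including empty envelopes — the count-closest rule
  is applied literally.
- Reserve coverage assumes mutually disjoint reserve polygons (true for the
  generator; overlapping real-world polygons would need a union step).
- With stratified folds and very small record counts, AUC estimates are
  noisy; the unusable-ensemble fallback (record cells only) keeps the
  pipeline total.
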