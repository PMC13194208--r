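---
title: "Measuring fragmentation change after habitat loss: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fragmentation change after habitat loss: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragchange)
```

`fragchange` quantifies how fragmentation changes when habitat is lost. This
vignette documents the measurement model, the parameters that matter, the
synthetic cohort generator, and the numerical and design decisions behind
them — the material a reader needs to judge what results from this package do
and do not show.

## The measurement model

The unit of analysis is a **landscape**: a circular window of radius $r$
around a sample point, cut from a binary habitat raster in a projected,
meter-unit reference. Cells are habitat, non-habitat, or outside the circle.
A cell belongs to the circle iff its center is within $r$ of the window
center (inclusive) — a simple, reproducible membership rule with no partial
cells. Out-of-extent circles are refused, never silently truncated, because a
clipped window would silently change the landscape area that the per-hectare
measures divide by (`partial = TRUE` makes clipping explicit when wanted).

Four class-level measures are computed per time point from one labeling pass:

- **Proportion in habitat** $p$: habitat cells over inside cells.
- **Patch number** PN: connected components of habitat. The default adjacency
  is the 8-neighbor queen rule, the convention most raster fragmentation
  software uses; rook (4) is available. The choice matters most for sparse,
  noisy habitat where diagonal links merge many small patches.
- **Edge density** ED (m·ha⁻¹): rook-adjacent habitat/non-habitat cell pairs,
  each contributing one cell side of length `cell_size`, divided by landscape
  area. Only pairs with *both* cells inside the window count: "habitat edge"
  means a boundary between two observed covers, so the circle's rim — where
  the second cover is unobserved — contributes nothing. A fully forested
  window therefore has ED = 0. Whether edge at the window rim should count is
  genuinely ambiguous in the field; counting it would add a radius-dependent
  offset to every landscape and make full-cover landscapes look fragmented.
- **Mean patch size** MPA (ha): habitat area over PN, and **defined as 0 when
  there is no habitat**. This convention keeps the exact conservation
  identity $\mathrm{PN} \times \mathrm{MPA} = p \times A$ (with $A$ the
  landscape area in ha) valid for every landscape including those that lose
  all habitat between years — the identity the test suite checks on every
  computed landscape at $10^{-9}$ relative tolerance.

Tree-height rasters become binary maps by an inclusive threshold
(`height >= 5` m by default, the FAO forest definition), with an optional
mask for cropland, built-up land, water, snow and ice. An optional
isolated-patch filter (`remove_small_patches()`) deletes patches at or below
a cell-count cutoff before measurement, as a sensitivity analysis against
single-pixel classification error; it defaults to off.

## The composite fragmentation index

The composite index summarizes PN, ED and MPA on a common [0, 1] scale,
fitted per landscape size on a cohort:

1. **Fences.** For each of the three metrics, Tukey fences are estimated from
   the *later* year's values: $Q_{upper} = Q_3 + k\,\mathrm{IQR}$ and
   $Q_{lower} = Q_1 - k\,\mathrm{IQR}$ with $k = 1.5$. Quartiles use linear
   interpolation between order statistics (`stats::quantile()` type 7, the
   most common default in scientific software; the estimator is
   configurable). Some published formulations print the lower fence as
   $Q_1 + k\,\mathrm{IQR}$, which sits *above* the median whenever the IQR is
   positive and thus caps values that are not low outliers at all; we treat
   the standard subtraction as the intended rule and expose the printed
   variant via `lower_fence_sign = "plus"` for literal fidelity.
2. **Winsorization.** Both years' values are clamped into
   $[Q_{lower}, Q_{upper}]$ — the same fences for both years, so the earlier
   year cannot move the outlier thresholds. `capped = FALSE` skips this step
   entirely (a sensitivity mode that keeps the full range of values).
3. **Normalization.** Each metric is min–max normalized to [0, 1]
   *within each year* by default, the literal reading of per-year scaling;
   because per-year bounds make cross-year level comparisons debatable,
   `norm = "pooled"` shares one set of bounds across both years. Whether the
   per-year or pooled convention is the "right" one is an open question;
   both are provided and the default is the per-year reading. If a metric is
   constant (bounds collapse), all values map to the neutral 0.5 so the
   degenerate component neither inflates nor deflates the index. Components
   computed for data outside the fitting cohort are clamped to [0, 1].

The index is then $(\mathrm{PN}' + \mathrm{ED}' + (1 - \mathrm{MPA}'))/3$,
monotone increasing in normalized patch number and edge density and
decreasing in normalized mean patch area.

## Change and classification

Loss is $p_{t0} - p_{t1}$; only landscapes with strictly positive loss are
retained, and the index is fitted on that retained cohort. Each measure's
change $x_{t1} - x_{t0}$ is oriented so positive means more fragmented (mean
patch size is multiplied by −1) and classified by sign. "No change" needs a
tolerance for the continuous measures: the default is an absolute
`eps = 1e-9`, small enough that only floating-point ties are absorbed, and
configurable for users who consider, say, a 0.1 m/ha shift ecologically
negligible. Patch number is an integer, so its tolerance is forced to exact
zero and the classification is invariant to `eps`.

Outcome summaries report, per group and measure, the percentage of retained
landscapes in each class. Grouping keys are landscape radius, initial cover
binned into 0.2-wide left-closed intervals (top bin closed so $p = 1$ is
included), loss magnitude binned into 0.1-wide right-closed intervals on
(0, 1], and biome. Percentages sum to 100 within each row by construction;
empty groups are omitted rather than reported as 0/0.

## The synthetic cohort generator

The generator stands in for global forest-change maps. It emulates the
features the analysis relies on: spatially autocorrelated binary habitat at a
controlled proportion, Landsat-like 30 m cells, two time points linked by an
explicit loss process, circular landscapes of several radii, and categorical
biome strata.

Surfaces come from **spectral synthesis**: white Gaussian noise filtered in
the Fourier domain so power decays as $f^{-\beta}$, with `roughness`
$= \beta$ mapping monotonically to spatial autocorrelation ($\beta = 0$ is
white noise). Spectral synthesis was chosen over midpoint displacement
because it is exactly seedable, dimension-agnostic, and gives independent
control of $\beta$. The surface is **rank-thresholded**: the top
$\mathrm{round}(p\,n^2)$ cells become habitat, so the realized proportion is
controlled to within $1/n^2$ rather than drifting with the surface
distribution.

Five loss kinds span the qualitative space between "loss fragments" and
"loss de-fragments": uniform random removal; erosion (repeatedly remove the
habitat cell with the most rook non-habitat neighbors, ties broken in
row-major order — deterministic without a second seed stream); whole-patch
removal in increasing size order (never splits a patch, so it can only
reduce the patch count, and stops short of the target rather than split);
dissection (a randomly placed row or column strip of width
$\max(1, \mathrm{round}(fH/n))$, clipped to the target count); and
perforation (interior cells only — four habitat rook neighbors — removed one
at a time, recomputing interiors, until the target or no interiors remain).
Habitat is only ever removed, and the realized fraction is reported because
patch removal and perforation can legitimately fall short.

Cohort defaults are the package's study conditions: 500 landscapes on 64×64
grids of 30 m cells, habitat proportion uniform on (0.15, 0.85), roughness
uniform on (0.5, 3), an equal mixture of the five loss kinds, per-landscape
target loss uniform on (0.02, 0.30) — observed two-decade forest-loss
fractions are mostly below 0.1 and losses above 0.3 are rare — and radii of
250 and 500 m, the largest circles that fit the default grid with margin.
Determinism follows a fixed splitting rule: all randomness for landscape $i$
(parameter draws, surface, loss realization) runs under seed
`master + i`, so cohorts reproduce byte-for-byte across machines from one
master seed, and records are independent of cohort size prefixes.

What the generator does **not** emulate: the geographic clustering of real
deforestation, tree-height dynamics and regrowth (no forest gain), mixed
loss processes within one landscape, georeferenced projection issues, and
classification noise. Passing tests therefore demonstrate that the
measurement and classification machinery is correct and that both increase
and decrease outcomes arise under plausible loss processes — not that any
particular real-world percentage is reproduced.

## Validation runs and problem sizes

The test suite validates labeling against an independent flood-fill oracle
on 200 random 20×20 grids per adjacency rule; the conservation identity on
1,000 random landscapes; scenario signatures on 50 seeded 64×64 replicates
at $p = 0.5$, $f = 0.1$ (whole-patch removal decreases the patch count in
every replicate that removed anything; perforation increases edge density in
every replicate that removed cells — each interior hole adds four edge
segments; dissection increases the patch count in a majority); and an
end-to-end 500-landscape mixed cohort in which every one of the four
measures shows both strictly positive increase and decrease percentages —
the qualitative point that habitat loss does not imply increasing
fragmentation. These sizes were chosen as the smallest cohorts at which the
signatures are unambiguous.

## Known limitations

- Rasters must already be projected in meter units; the package refuses
  rather than reprojects, and TIFF input takes its geotransform from the
  caller because the reader parses pixels only.
- Edge length is rook-based cell-side counting; no perimeter smoothing or
  diagonal edge lengths.
- The four measures are the package's scope; core-area, proximity or
  aggregation indices are not computed.
- Summaries are descriptive frequencies; no inferential statistics are
  attached.
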