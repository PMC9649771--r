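---
title: "Methods: stacked trait-decile distribution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked trait-decile distribution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices behind
`traitstack`, in the order the pipeline applies them. Everything stated here
about behaviour is exercised by the test suite; quantities such as AUC bands
or recovery scores are computed by `scripts/acceptance.R` and the tests, not
asserted here.

## Grids, rasters and coordinates

Rasters are regular geographic grids of square cells (degrees). The package
uses a single convention throughout: 0-based `(row, col)` indices with row 0
at the north, and half-open cells, so a point on an interior cell edge
belongs to the cell south/east of the edge and points on the outer
east/south boundary are out of extent. The floor rule makes spatial thinning
deterministic; no tie ever depends on floating-point luck. Coordinates are
taken as given (one shared CRS is a precondition); the package performs no
reprojection or resampling.

Raster I/O uses the ESRI ASCII grid format: single band, explicit nodata,
plain text. Integer layers (binary, richness, change maps) round-trip
bit-exactly; continuous layers are written with 15 significant digits.
Internally a single nodata convention is used — a validity mask on the
stack, with masked cells ignored by every consumer — and mapped to the
format's nodata value on write.

## Trait deciles

Genotypes are sorted by `(leafout_day, genotype_id)` and cut at the ideal
boundaries $i \cdot n / 10$: position $p$ ideally belongs to bin
$\lceil 10 p / n \rceil$. Because a trait value may not span two deciles, a
tie group straddling a boundary moves entirely into the earlier (lower)
decile. This keeps decile 1 — the earliest 10% of leaf-out — maximal, and is
the only rule consistent with both constraints. Bin sizes are whatever the
cut produces; there is no rebalancing. Note that heavy ties can legitimately
leave a decile empty even with ten or more distinct trait values (a tie
group can swallow more than one boundary); the package errors when fewer
than ten distinct values exist and warns otherwise.

Thinning keeps, per decile, the first genotype in `(leafout_day,
genotype_id)` order in each grid cell. The duplicate-choice rule is
arbitrary but deterministic; the same cell may appear in several deciles'
presence sets, which is intended — the decile models are independent.

## The presence-background model

Each decile's model is the weighted-logistic formulation of maximum-entropy
presence-background modelling: a logistic regression of presences (total
mass 1) against background cells (total mass 100), ridge-penalized with
$\lambda$ (default 1) on standardized features. As the background mass grows
the solution approaches the maximum-entropy fit; mass 100 is close enough
that the remaining difference is far below the Monte Carlo noise of the
background sample, while keeping the fit an ordinary penalized GLM solved by
Newton/IRLS (iteration cap 500; exceeding it is an error carrying
diagnostics, not a silent result). Normalizing the presence mass makes the
fit exactly invariant to duplicated presence rows.

Design choices:

* **Features**: linear + quadratic in each standardized layer by default.
  With ~34–46 presences per decile, richer classes invite overfitting;
  product and hinge features exist behind the `feature_spec()` switch.
  Normalization constants (mean, sd per layer) are estimated from the
  background sample at fit time and stored in the model; projection onto a
  future stack reuses them verbatim, so predictions depend only on layer
  values and stored constants.
* **Background**: ~10,000 cells sampled uniformly without replacement from
  the valid landscape (all of them if fewer exist). Presence cells are not
  excluded — the presence-background convention — and this is configurable.
* **Logistic output**: suitability is
  $s(x) = \mathrm{plogis}(\eta(x) - E_q[\eta])$ with $q$ the fitted
  exponential distribution over the training background. This is the
  maximum-entropy logistic output at default prevalence 0.5: an
  uninformative model scores exactly 0.5 everywhere, and the intercept
  cancels.
* **Evaluation**: seeded 5-fold cross-validation of the presences; each
  held-out fold is scored against the full background (presence-background
  test AUC, rank-based with half credit for ties). The final model is
  refitted on all presences for the training AUC.
* **Threshold**: the 10% training-presence rule. $\tau_{10}$ is the largest
  training-presence suitability whose strictly-below fraction is at most
  10% (nearest-rank); cells with suitability $\ge \tau_{10}$ are suitable.
  Omission can therefore never exceed 10%, and equals 10% only when the
  presence scores are distinct enough. This threshold is deliberately
  liberal: binary maps retain ~90% of the training signal and over-predict
  rather than under-predict, which matters when interpreting the recovery
  scores below.
* **Variable importance**: permutation importance (drop in training AUC when
  one layer's values are permuted across the evaluation points, averaged,
  floored at zero, normalized to 100%). Path-based "percent contribution"
  is specific to one fitting algorithm; permutation importance is defined
  for any fit. This is a deliberate deviation from the original software's
  reporting.

## Stacking, change and summaries

Decile richness is the cell-wise sum of the ten binary maps (nodata
propagates). Change is `future − current` per cell; cells with current
richness 0 are flagged so a zero change is not read as stability. Net loss
is `% cells with negative change − % cells with positive change`; magnitude
is tabulated separately because a loss of 2 and a loss of 7 both count once
as a loss. The default denominator is every valid cell of the reporting
extent; a suitable-only variant (cells with current richness ≥ 1) is
available because both readings of "percent of the landscape" are useful.
Per-population summaries use latitude-band extents on the synthetic
landscape (watershed stand-ins); with the all-valid rule they are exactly
area-weight additive to the range-wide summary. Printed percent-area values
round half-up to one decimal. GCM averaging is a reporting-layer mean with a
t-based 95% interval over the (three) GCM values — an approximation, since
per-GCM spread is the only variance source it sees.

## Trait communities, similarity, ordination

A suitable cell's decile set is encoded as a 10-bit mask (bit $d-1$ ⇔
decile $d$), a bijection with the 1023 non-empty combinations; richness-0
cells are excluded, never encoded. Cell similarity is
$1 - \bar d / 9$ where $\bar d$ is the mean pairwise distance between the
present decile indices: 1 for singletons, 0 only for the extreme pair
\{1, 10\}. The scenario score is the count-weighted mean over cells (the
weighting is a package choice; averaging over distinct combinations instead
would ignore how much landscape each combination occupies). A positive delta
against the population's current baseline means narrowing local trait
ranges — convergence.

The RDA is implemented directly: column-centre the count matrix, project it
onto the dummy-coded constraints by least squares, and report the
constrained variance fraction (fitted sum of squares over total). The
permutation p-value permutes constraint rows (seeded); term tests inside
stepwise selection use the reduced-model residual-permutation scheme with a
pseudo-F statistic, which keeps tests of one factor valid in the presence of
others. Counts enter raw and centred by default; a Hellinger transform is
available but off. Stepwise selection adds the most significant candidate
below $\alpha = 0.05$, then drops any term whose marginal test given the
rest is no longer significant, to a fixed point, with a cycle guard. A
saturated factor leaves no residual degrees of freedom and is never
testable, hence never selected. One structural caveat: the baseline
scenario's sentinel levels make the GCM, RCP and period factors partially
collinear (a "none" level in one equals "current" in another), so the
pipeline prunes the final constraint set to a full-rank subset; the
module-level `rda_communities()` instead raises an explicit aliasing error,
because silently dropping user-supplied constraints would misreport what was
tested.

## The synthetic landscape

The generator emulates the statistical structure the analysis assumes, not
any particular geography:

* Four continuous layers (`cmi`, `ppt_wt`, `rh`, `td`) built as a
  latitudinal gradient plus bilinearly interpolated coarse Gaussian noise;
  a Strahler-ordered stream network rasterized from a random spanning tree
  on a coarse lattice (the simplest structure that makes habitat riparian
  and dendritic).
* 400 genotypes in three latitudinal populations (57/157/186, south to
  north), placed only on stream cells. Leaf-out day = baseline +
  $\sum_j \beta_j z_j$ + population offset + Gaussian noise, rounded half
  away from zero and clipped to days 71–125 (a 54-day span). Signs follow
  the observed relationships: earlier leaf-out with higher moisture index
  and winter precipitation, lower relative humidity and continentality.
* Future scenarios are additive layer shifts scaled by GCM, RCP and period
  factors — never resimulated noise — so planted-niche change is exactly
  computable. The default grid is 150 × 100 cells at 0.05°, sized so the
  full 13-scenario pipeline runs in seconds on one CPU.
* Seeding: a master seed spawns named substreams (environment layers,
  stream network, populations, background, CV folds per decile, selection,
  ordination), so changing one stage's draws never perturbs another's.

Calibration: effect sizes are not published, so the defaults were chosen
once so that the fitted decile models evaluate in the test-AUC band the
method is expected to reach (≈0.8–0.9): a dense stream network (coarse
spacing 3 cells — at ~1 km resolution most riparian-corridor cells touch a
stream), residual trait noise of 8 days, and a dominant moisture-index
coefficient of −5 days/sd. The scenario shift magnitudes were likewise fixed
once to give a moderate range-wide contraction rather than collapse. What
the generator does **not** emulate: realistic GCM climate fields, spatial
autocorrelation structure of real bioclimate beyond smooth noise, gene flow
or explicit genetics (population offsets stand in for genetic structure),
and observation error in occurrences. Passing tests therefore demonstrate
that the pipeline recovers structure of this idealized kind, not that any
real landscape obeys it.

## The planted-niche recovery experiment

`recovery_experiment()` makes the truth knowable: the trait depends only on
the moisture index (small residual noise), so trait deciles correspond to
bands of that driver, and a single future scenario applies a uniform driver
shift. The truth record partitions the driver over stream cells into ten
bands, widened by half a band-width per side — `plant_decile_niches()`
defaults to equal-width bands of the value range; the recovery experiment
uses equal-count (quantile) bands, the exact counterpart of equal-count
trait deciles under a monotone trait-driver link.

Two recovery scores are reported. *Agreement* is per-cell set compatibility:
a stream cell agrees when the fitted and true decile sets share at least one
decile or both say the cell supports none. *Proportion correct* is the
stricter per-(cell, decile) binary accuracy; because the 10%
training-presence threshold intentionally over-predicts, this score is
structurally capped well below 1 and is reported for transparency rather
than thresholded. Net loss under the shift is compared with the analytic
oracle loss computed from the planted bands, both over all valid cells.

## Numerical conventions and degenerate inputs

* Rounding: trait days round half away from zero; percent areas round
  half-up to one decimal; nothing else is rounded.
* IRLS: convergence when the max coefficient update drops below 1e-8;
  variance weights floored at 1e-12 to survive separation.
* Degenerate inputs raise classed errors: constant layers (sd 0) at
  normalization, fewer than ten distinct trait values, empty background,
  out-of-extent occurrences, rank-deficient constraints, empty extents.
* All stochastic stages take explicit seeds; identical configs reproduce
  every output byte-for-byte (the run manifest records a config hash).

## Problem sizes

Tests and the acceptance script run the full pipeline at the default
150 × 100 grid (15,000 cells, ~10,000 background points, 10 decile models ×
6 fits each) and scaled-down 60 × 40 grids for structural checks — sizes
chosen so the whole suite exercises every stage, including two full pipeline
runs and 500-replicate permutation calibrations, in well under a minute of
fitting time on a single CPU.

## Known limitations

* The maxent analogue is a penalized GLM with linear+quadratic features; it
  will not reproduce the original Java implementation's fits, thresholds or
  path-based variable contributions bit-for-bit, and does not implement
  clamping/extrapolation diagnostics (MESS maps) or ensembles.
* The published omission rates imply tie conventions of the original
  software that the nearest-rank rule does not reproduce exactly (it
  guarantees ≤ 10% instead).
* The similarity score's formula is a fixed interpretation ("average
  distance between observed trait deciles", rescaled so higher = narrower);
  published similarity values are not reproduction targets.
* RDA results depend on untransformed, centred counts; the published
  constrained fractions (51.9%/64.7%) are not reproduction targets since
  the original transform is unstated.
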