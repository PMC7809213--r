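---
title: "Methods: maximum-entropy ensemble modelling of invasive-species ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy ensemble modelling of invasive-species ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the screening and ensemble
procedure, the synthetic-data generator, and the numerical and design
choices behind `sdmensemble`. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## Why presence-background, and why subset screening

Invasive species are out of equilibrium with climate: absence of records in
a region may reflect dispersal limitation rather than unsuitability, so
true absences are not observable and presence-only methods are the
appropriate tool. The package models suitability with a Gibbs
(maximum-entropy) distribution contrasted against background points, and
judges candidate models not by fit in the native range but by *spatial
transfer*: can a model calibrated outside a recently invaded region predict
the occurrences inside it? Small variable subsets (4–5 bands) are screened
exhaustively because models with many correlated bioclimatic predictors
overfit, and overfitting is most damaging when the model is projected onto
future climates.

## The maximum-entropy core

Given presence cells $x_1 \dots x_m$ and a background sample
$b_1 \dots b_N$, the model is
$q_\lambda(x) = e^{\lambda^\top f(x)} / Z_\lambda$ with
$Z_\lambda = \sum_{k} e^{\lambda^\top f(b_k)}$, fitted by maximizing

$$\ell(\lambda) = \tfrac1m \textstyle\sum_i \lambda^\top f(x_i)
  - \log Z_\lambda - \sum_j \beta_j |\lambda_j|.$$

**Features.** Linear, quadratic, product, hinge (forward and reverse) and
threshold transforms of the raw bands, min–max scaled to $[0,1]$ on the
background; out-of-range projection inputs are clamped. Hinge/threshold
knots sit at 30 interior background quantiles per band (a tractable
stand-in for per-datum knots, recorded in the model so results are
reproducible); a band constant over the background contributes no
hinge/threshold features.

**Penalties.** $\beta_j$ = multiplier × class base × $s_j/\sqrt{m}$, where
$s_j$ is the feature's SD at the presences (floored at $10^{-3}$) and the
class base follows the published MaxEnt defaults (linear/quadratic/product
interpolated over presence counts 0/10/30/100 from 1/1/0.2/0.05; hinge 0.5;
threshold 2→1). A multiplier of zero is rejected: with all
$\beta_j > 0$ the optimum is finite even under complete separation.

**Optimizer.** Proximal-gradient ascent (soft-thresholding) with
Barzilai–Borwein spectral steps, safeguarded by backtracking so the
penalized objective never decreases — this ascent property is tested, and
the fitted coefficients are checked against an independent dense
grid-search oracle on small problems. Default stopping: objective
improvement below $10^{-7}$ or 500 iterations; invariance tests that
compare two fits of the same mathematical problem (e.g. band rescaling)
tighten this to $10^{-14}$, because at loose tolerance the two optimization
paths stop at measurably different points of a flat optimum.

**Outputs.** `raw` is $q_\lambda$ normalized over the fitting background
(sums to 1 there, a tested invariant). The default thresholding scale is
`cloglog`, $1 - \exp(-e^H \cdot \mathrm{raw})$ with $H$ the entropy of the
raw distribution — the modern MaxEnt default; `logistic` is available
because older MaxEnt versions used it.

**Tuning.** AICc with the Warren–Seifert bookkeeping: likelihood from raw
values renormalized to sum to one over the background, $k$ = number of
nonzero coefficients, $\mathrm{AICc} = 2k - 2L + 2k(k+1)/(n-k-1)$, infinite
when $n \le k+1$. The default grid is 8 multipliers (0.5–4 by 0.5) × six
feature-class sets (L, LQ, H, LQH, LQHP, LQHPT); plain AIC is available by
flag since the motivating study says "AIC" while its cited method defines
AICc. Ties break toward fewer feature classes, then a smaller multiplier
(an explicit rule keeps runs reproducible).

## Evaluation conventions

* **AUC** is the rank-sum probability that a random presence outscores a
  random background point, ties counted one half.
* **TSS** uses background points as pseudo-absences (the only option
  without true absences): sensitivity = fraction of test presences ≥ t,
  specificity = fraction of background < t. The optimal threshold scans all
  unique observed scores; ties resolve to the smallest threshold.
* **Omission** of the held-out region is the fraction of its records
  scoring strictly below the threshold; the screening gate demands
  omission 0 ("100 % predicted"). A record exactly at the threshold counts
  as suitable (≥ convention) — this choice matters for that gate and is
  deliberately prominent here.
* The held-out-region check uses the TSS-optimal threshold of the same
  replicate's test split; no separate threshold rule is defined for it.

## Two-step procedure and ensemble bookkeeping

Screening fits use a fixed configuration (default: LQH features,
multiplier 1); the AICc search runs *between* the steps, on the non-holdout
occurrence set, and step 2 reuses the tuned parameters per subset — tuning
is not repeated after the held-out region's records are added. Replicate
seeds derive from `hash(master_seed, subset_id, replicate_id)`, so adding
subsets never perturbs existing replicates and a fixed master seed makes
the whole pipeline bit-reproducible.

Subset enumeration defaults to **all** size-4 and size-5 combinations (792
for 11 bands). The motivating study reports 126 datasets from the same
grouping rule; no stated enumeration rule produces 126, so the
discrepancy is documented rather than silently resolved, and a constraint
hook (`enumerate_subsets(..., constraint =)`) lets users reproduce any
restricted scheme.

Consensus maps store the exact vote fraction (vote count / model count), so
"unanimous" is testable as exactly 0 or 1 without float-equality fragility;
the SD layer is the population SD of the 0/1 votes, zero exactly at
unanimity. The current-climate consensus averages only the step-2
survivors (AUC > 0.7), with the count logged — pooling all replicates
instead is a defensible alternative convention.
Future binarization reuses each model's current-climate threshold;
per-(RCP, year) consensus pools all subsets × replicates × GCMs, with
per-GCM sub-consensus retained for the centered deviation maps. An empty
retention list (no subset passes step 1 — the outcome the motivating study
reports for one of its two species) terminates the pipeline cleanly with a
"no dataset retained" report and no downstream stage runs.

Area fractions default to cosine-latitude weighting (equal-angle cells
shrink poleward); cell-count weighting is kept as an option because
neither convention is canonical, and the report emits both.

## The synthetic study

The generator replaces WorldClim rasters and curated occurrences with
objects having the statistical structure the analysis assumes:

* **Climate stack**: each band = shared latitudinal/longitudinal gradients
  with band-specific random weights (inducing inter-band correlation) plus
  a Gaussian random field (white noise smoothed with a kernel of width
  `correlation_length` cells). Defaults: 100 × 100 cells, 11 bands named
  after the bioclim variables used in the motivating analysis,
  correlation length 6 cells.
* **Virtual species**: suitability = inverse-logit of a linear predictor
  on standardized driver bands (defaults: drivers bio10 and bio12,
  coefficients 8 and 6, intercept −12). These values were chosen once so
  that the species occupies a restricted climatic envelope (~6–7 % of
  cells), as is typical of an invader with a well-defined niche; with a
  widespread species the theoretical ceiling on presence-background AUC
  (which falls with prevalence) would sit below the screening gate and no
  subset could demonstrate transferability. Standardization constants come
  from the current-climate stack and are reused verbatim on future stacks,
  mirroring projection of a fitted model.
* **"Europe analogue"**: the held-out invasion region is the square window
  (default edge 12 % of the grid) with the highest mean suitability —
  a compact region of clearly favourable climate the species reached late.
  Its occurrence count is small (default 15) as befits a recent invasion.
* **Occurrences**: cells drawn without replacement with probability
  proportional to suitability, placed at cell centers so per-pixel
  thinning is exactly predictable. Defaults: 200 native records.
* **Pseudo-GCMs**: per-GCM smooth offset fields whose spatial pattern
  depends only on (GCM code, seed) and whose amplitude scales with
  radiative forcing (×RCP/8.5) and horizon ((year−2030)/40) — so offset
  magnitude is ordered 2.6 < 4.5 < 6.0 < 8.5 and 2050 < 2070 by
  construction, and ensemble spread across GCMs is genuine spatial
  disagreement, not noise.

What the generator does **not** emulate: the true covariance of bioclim
variables, coastline/land masking, downscaling physics, sampling bias in
occurrence records, and non-additive climate change. Passing tests
therefore demonstrate that the pipeline's statistics and bookkeeping are
correct and that a recoverable signal is recovered — not that any real
species' range is predicted well.

## Numerical choices and degenerate inputs

* Point-to-cell mapping uses half-open cells $[x, x+\Delta) \times
  (y-\Delta, y]$: a point on a shared edge belongs to exactly one cell, and
  the northern grid edge belongs to row 1. Thinning keeps the first record
  per cell in input order (deterministic and auditable; any single
  survivor per pixel is equally valid).
* Cropping keeps cells whose centers fall in the *closed* window. On a
  global 1° grid the focal window 20° W–50° E × 27.5° N–70° N therefore
  spans 70 columns × 43 rows — 27.5° N is itself a half-degree cell center
  on the closed boundary.
* Rasters travel as multi-page 32-bit TIFF (bands min–max scaled to [0,1];
  a validity mask as the final page) with a JSON sidecar for band names,
  ranges, affine transform and nodata; round trips are exact to well below
  $10^{-6}$. Model serialization (lambdas table + JSON header) round-trips
  predictions to $10^{-12}$.
* Background sampling is uniform without replacement over the extent mask
  ("randomly generated" is deliberately minimal); requesting exactly the
  number of valid cells returns them all, requesting more fails with the
  achievable count.
* `subset_id` is the sorted band names joined with `+`: stable, unique and
  human-readable, which makes record tables auditable without a lookup.

## Problem sizes used by the tests and scripts

The packaged analysis and the acceptance script run the study at reduced
scale — 60 × 60 cells, 6 bands (21 subsets), 3 replicates, 2 pseudo-GCMs,
4 RCPs, 2 horizons, 2,000 background points — which preserves every
structural property of the full design (the task census at the published
shape, 14 × 10 × 11 × 4 × 2 = 12,320, is verified arithmetically). The
recovery tests use the full synthetic defaults (100 × 100 cells, 200
presences, 10,000 background points). These sizes are the package's own
choice of a desk-scale experiment; nothing in the method depends on them.

## Known limitations

* No reprojection between CRSs, no vector data, no MESS-style
  extrapolation diagnostics, no categorical predictors.
* TSS against background pseudo-absences is prevalence-dependent in ways
  TSS with true absences is not; gate values are conventions, not
  statistical guarantees.
* The proximal-gradient optimizer is exact but first-order; on strongly
  collinear hinge dictionaries it needs tight tolerances to resolve the
  flat optimum direction (the defaults are fine for screening decisions,
  which depend on predictions, not coefficients).
* The empirical 126-dataset count of the motivating study cannot be
  reproduced from its stated rule; see above.
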