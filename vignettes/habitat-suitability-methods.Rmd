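---
title: "Penalized maximum-entropy habitat suitability: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized maximum-entropy habitat suitability: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemax)
```

`nichemax` implements a complete presence-only habitat-suitability
workflow of the kind used to map fungal, plant and animal distributions
from occurrence records and bioclimatic raster layers, together with a
virtual-species simulator that makes every stage testable against known
ground truth. This vignette is the package's account of the science: the
model, the parameters that matter, the numerical choices, and what the
synthetic experiments do and do not demonstrate.

## The model

Presence-only data tell us where a species was found, not where it was
absent. The maximum-entropy approach treats the species' distribution as
a probability density over landscape cells and picks, among all densities
consistent with the occurrence data, the one closest to uniform. With
features $f_j(x)$ derived from the environmental covariates at cell $x$,
the density is the Gibbs distribution

$$P_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda},
\qquad Z_\lambda = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)},$$

and the coefficients maximize the L1-penalized presence log-likelihood

$$\frac{1}{m}\sum_{i=1}^m \lambda \cdot f(x_i) \;-\; \ln Z_\lambda
\;-\; \sum_j \beta_j |\lambda_j|.$$

The penalty is what keeps the model from chasing sampling noise. Each
feature's $\beta_j$ follows the conventional default rule
$\beta_j = \mathrm{rm} \cdot \beta_0(\text{class}, m) \cdot s_j / \sqrt{m}$:
$\beta_0$ interpolates published sample-size tables
(linear/quadratic/product 1.0 below 10 presences falling to 0.05 at 100;
hinge constant 0.5; threshold 2.0 falling to 1.0), $s_j$ is the feature's
standard deviation over the $m$ presences (floored at 0.01 so nearly
constant features stay penalized), and the regularization multiplier
`rm` is the single user-facing smoothness dial. The $s_j/\sqrt m$ factor
matters: it puts the penalty on the same scale as the sampling error of a
feature mean, and without it the penalty overwhelms the attainable
likelihood gain at realistic sample sizes.

Feature classes follow the field's convention: **L**inear (min-max
scaled to $[0,1]$ on the background), **Q**uadratic, **P**roduct,
forward/reverse **H**inge at background-quantile knots (50 per variable
by default), and **T**hreshold indicators (20 knots). Out-of-range
prediction values are clamped to the training bounds.

Reported suitability uses the cloglog transform
$1 - \exp(-e^{H} \cdot P_\lambda(x))$, with $H$ the entropy of the fitted
raw distribution, which maps an uninformative model to
$1 - e^{-1} \approx 0.632$ everywhere; the older logistic variant is
available behind a flag.

## Fitting and its verification

The objective is concave, so cyclic coordinate descent with a
soft-thresholded Newton step per coordinate (backtracked so the
penalized objective never decreases) converges to the global optimum;
convergence is declared when a full sweep improves the objective by less
than `tol = 1e-5` relatively (500-sweep cap, an error if exceeded — the
cap is generous for the convex problem, and hitting it indicates a
degenerate configuration such as two presences with nearly unbounded
coefficients). Three independent routes verify the solver in the tests:
a dense grid search over the same objective on one- and two-feature
problems (agreement to $10^{-3}$), the Karush-Kuhn-Tucker conditions of
the L1 optimum, and an L1-penalized Poisson log-linear fit via `glmnet`
(the two problems share their optimum at penalty $\frac{m}{N}\beta_j$
when presences sit on background cells).

## The pipeline stages and their parameters

* **Thinning** (`thin_by_grid`): at most one record per cell of a 5 km
  grid (1° latitude = 111.32 km; longitude cell width widened by
  $1/\cos(\text{latitude band})$). The retained record is the first in
  input order — "most representative" is not well-defined from
  coordinates alone, and first-in-order is deterministic. The grid
  anchors at `(floor(min lon), floor(min lat))` so results are
  data-local but reproducible.
* **Screening** (`select_variables`): Pearson correlations over all
  jointly valid landscape cells (a point-sample mode exists); iterative
  rounds drop, from each offending pair with $|r| > 0.8$, the variable
  ranked less important until the retained set is pairwise clean. The
  rank comes from permutation importance of a preliminary all-variable
  linear fit. With a fixed sample the survivors' correlations never
  change, so the deterministic procedure cleans in one recomputation
  round; the audit trail records every removal and its cause.
* **Tuning** (`model_selection`): every combination of the
  regularization grid (default 0.1, 0.5, 1, …, 6 — thirteen values) and
  feature-class grid (L, LQ, H, LQH, LQHP, LQHPT) is fitted on the full
  presence set and scored by
  $\mathrm{AICc} = 2k - 2\ln L + \frac{2k(k+1)}{n-k-1}$ with $k$ the
  nonzero-coefficient count and the likelihood renormalized over the
  whole landscape (the convention of standard SDM tuning tools, so
  background subsampling does not distort comparisons). Spatial-block
  cross-validation (median-longitude then median-latitude splits into
  four quadrants) supplies test-AUC and omission diagnostics alongside.
  Ties go to fewer parameters, then stronger regularization.
* **Importance**: percent contribution credits each coordinate update's
  penalized-gain change to the updated feature's source variable
  (products split 50/50) — a path-dependent measure, deterministic here
  because the solver is; duplicated variables will hand their shared
  credit to whichever is updated first, so interpret contributions
  jointly with permutation importance (AUC drop under shuffling,
  10 seeded repetitions) and the jackknife of with-only/without-one
  training gains.
* **Mapping**: four equal-interval suitability levels with left-closed
  intervals ([0, 0.30) unsuitable, [0.30, 0.50) low, [0.50, 0.70)
  moderate, [0.70, 1] high — closure chosen so "> 0.70 is high" holds and
  every value has exactly one class); spherical cell areas
  $(111.32\,\text{km} \cdot \text{cellsize})^2 \cos(\text{lat})$, within
  0.6% of ellipsoidal values at mid-latitudes; percent changes rounded
  half-up to 2 decimals, the convention that reproduces published area
  tables; range centroids are area-weighted means of suitable-cell
  centers (binary mask at suitability ≥ 0.30 by default), and shifts are
  haversine distances on a 6371 km sphere with initial bearings.

## The virtual-species experiments

`virtual_preset()` fixes the canonical study: a 200 × 200 landscape of
0.05° cells (a 10° square anchored at 100°E, 20°N), four Gaussian-
random-field layers with a 10-cell correlation length — desk-scale, yet
large enough for quadrant blocking — one layer mixed 70/30 with a
south-to-north gradient so scenario shifts have a geographic direction.
The species responds to two of the four layers through Gaussian niches
(optima 60 and 25, breadths 8 and 6 on ranges 0–100 and 0–50), which puts
high-truth habitat on roughly a tenth of the landscape — a typical
virtual-species prevalence that leaves both presence and absence
environments well represented. 200 presences are drawn
size-biased by truth at cell centers (unjittered, so thinning tests are
exact). The bundled scenario subtracts 15 units from the gradient layer,
moving its favorable band north by a known amount.

The acceptance experiments run this preset end-to-end over five seeds
with a compact tuning grid ({0.5, 1, 2} × {L, LQ}) and the default
10,000-cell background: held-out AUC above 0.85 (the truth surface
itself scores ≈ 0.90, so the fitted model sits close to the attainable
ceiling), response-curve optima within half a niche breadth of the
planted optima, and the suitable-range centroid moving north under the
scenario in at least four of five seeds. Quadratic need is checked
separately: with a unimodal planted response, AICc prefers LQ over L.

What these experiments do **not** show: robustness to the sampling bias,
spatial autocorrelation of errors, covariate measurement error and
inter-layer correlation structure of real climate data (the simulator's
layers are mutually independent by default), or transferability beyond
the training extent. The synthetic scenario is an additive shift, not a
general-circulation-model projection.

## Degenerate inputs and numerical conventions

Constant variables are rejected where they would make a statistic
undefined (Pearson r, feature scaling). Raw predictions renormalize over
the fitted background and are checked to sum to 1 within $10^{-9}$ after
every fit. AICc is flagged invalid when $n - k - 1 \le 0$ and such rows
are excluded from selection. Coincident centroids report distance 0 with
a flagged bearing. NODATA handling is exact-equality on the declared
sentinel, intersection-masked across layers. All randomness (background
sampling, folds, permutations, simulation) flows from explicit seeds;
helpers save and restore the caller's RNG state.

## Known limitations

The solver is pure R and comfortable up to a few thousand features;
very dense hinge bases over many variables would benefit from a compiled
inner loop. Only geographic (unprojected WGS84) rasters are supported —
inputs must be pre-aligned, as reprojection is out of scope. The
percent-contribution measure inherits MaxEnt's path dependence by
design. Confidence intervals on importance tables are provided by a
seeded occurrence bootstrap and make no claim to match any particular
published resampling scheme.
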