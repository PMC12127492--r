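# nichemax

Presence-only habitat-suitability modelling for spatial ecology: an
L1-penalized maximum-entropy (Gibbs) niche model with the complete
workflow around it — occurrence thinning, bioclimatic-layer screening,
AICc tuning, suitability mapping, climate-scenario comparison and
range-centroid tracking — plus a virtual-species simulator so the whole
pipeline can be exercised and validated against known ground truth
without downloading climate data.

It is written for ecologists who model species distributions from
occurrence records (fungi, plants, animals) and for methodologists who
want an SDM stack whose every stage is unit-tested against independent
oracles.

## The model

Given presence cells $x_1,\dots,x_m$ and a background sample of the
landscape, the suitability model is the Gibbs density
$P_\lambda(x) = e^{\lambda\cdot f(x)}/Z_\lambda$ over cells, with
features $f$ built from the environmental layers (linear, quadratic,
product, hinge, threshold classes). Coefficients maximize the penalized
log-likelihood

```
(1/m) Σᵢ λ·f(xᵢ) − ln Z_λ − Σⱼ βⱼ|λⱼ|,   βⱼ = rm · β₀(class, m) · sⱼ/√m
```

solved by soft-thresholded coordinate descent (convex, verified against
brute-force grid search, KKT conditions and an independent L1 Poisson
solver). Suitability is reported on the cloglog scale
`1 − exp(−e^H · raw)`. The regularization multiplier `rm` and the
feature-class set are tuned by `AICc = 2k − 2lnL + 2k(k+1)/(n−k−1)` over
a configurable grid. Maps are classified at 0.30/0.50/0.70 into
unsuitable/low/moderate/high, areas use cos-latitude spherical cell
weights, and range centroids and their great-circle shifts summarize
scenario change.

## Worked example

The `analysis/` scripts run the whole study on simulated data:

```sh
Rscript analysis/01_simulate.R       # landscape + virtual species + presences
Rscript analysis/02_fit_pipeline.R   # thin -> screen -> tune -> fit -> map
Rscript analysis/03_report.R         # headline tables under results/tables
```

The same run in R:

```r
library(nichemax)

pre   <- virtual_preset(seed = 1)
stack <- generate_landscape(pre$landscape)
occ   <- sample_presences(true_suitability(stack, pre$species), 200,
                          seed = pre$species$seed)

cfg <- pipeline_config(occ, stack, out_dir = "results/run",
                       rm_grid = c(0.5, 1, 2), fc_grid = c("L", "LQ"),
                       scenarios = pre$scenario_deltas, seed = 1)
res <- run_pipeline(cfg)
#> thin: 200 -> 199 records
#> screen: 4 -> 4 variables in 0 round(s)
#> tune: selected fc=LQ rm=0.5 (delta AICc grid of 6)
#> fit: train AUC 0.871, mean CV test AUC 0.865

res$response_curves$env1$optimum   # recovered niche optimum (planted: 60)
#> [1] 60.65305
res$centroid_shifts
#>            scenario distance_km bearing_deg
#> northward northward    187.1033    9.656789
```

Read: thinning removed one co-gridded record; AICc picked the
linear+quadratic basis (the planted niche is unimodal) at rm = 0.5; the
model discriminates presences from background at held-out AUC ≈ 0.87
(the truth surface's own ceiling is ≈ 0.90); the recovered optimum for
`env1` misses the planted 60 by 0.65, a small fraction of the planted
niche breadth of 8; and under the scenario that moves the favorable
climate band north, the suitable-range centroid moves 187 km at bearing
≈ 10° — nearly due north, as planted. (Numbers from the seed-1 run;
other seeds vary within sampling error.)

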