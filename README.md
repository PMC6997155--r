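# cpforage

Foraging-habitat-quality analysis for central-place foragers.

`cpforage` links GPS telemetry of colonial central-place foragers (the
motivating system is a breeding seabird feeding on a patchily distributed
schooling fish) to a prey species-distribution surface, and asks whether
the birds' occupied foraging patches improve over the breeding season
faster than the landscape itself does. It implements the full chain as
tested, reusable R functions:

1. **Trip processing** — de-duplication, isolation of complete same-day
   colony-to-colony foraging trips, and rediscretization of each track to
   regular 200 m along-path intervals.
2. **Area-restricted search (ARS) detection** — first-passage time (FPT):
   for a circle of radius *r* centered on each track point, the time
   between the backward and forward first crossings. The characteristic
   foraging scale is the radius (scanned over 100–5000 m in 100 m steps)
   maximizing the across-bird mean variance of log FPT; points in the 90th
   percentile of FPT at that scale are the foraging locations.
3. **Prey distribution model** — a maximum-entropy presence-background
   model fit by coordinate descent on the L1-regularized convex objective
   −mean<sub>presence</sub>(βᵀf) + log Σ<sub>background</sub> e^{βᵀf} +
   Σ<sub>j</sub> π<sub>j</sub>|β<sub>j</sub>|, with linear, quadratic,
   product, and hinge features, a regularization multiplier of 2, 10-fold
   cross-validation with Mann–Whitney AUC, percent contribution and
   permutation importance per variable, and complementary log-log
   ("cloglog") suitability 1 − exp(−e^H p_raw) ∈ (0, 1).
4. **Null model** — 10,000 simulated foraging locations built by
   independently resampling timestamps, colony bearings, and colony
   distances from the observed foraging points (marginals preserved, joint
   structure broken), annotated and scored identically to the real points.
5. **Trend inference** — trip-mean suitability as the response of a beta
   regression additive model (logit link): group and year as parametric
   terms, group-specific penalized cubic-regression-spline smooths of
   Julian day, bird identity as a random intercept (via `mgcv`, REML);
   pointwise difference-of-smooths estimates D(d) = x_diff β̂ with
   approximate 95% intervals from the coefficient covariance; pairwise
   Wald χ² year contrasts; a per-sex body-condition index and an
   individual-trait mixed model.
6. **Synthetic world** — seeded generators for environmental raster
   stacks (SST, chlorophyll-a, salinity, bathymetry), thinned prey
   presences, bird metadata, and two-mode (transit/ARS) central-place
   tracks with known ground truth, so every stage is testable end to end
   without any field data.

## Worked example

The packaged demo runs the whole pipeline on a small synthetic two-year
scenario (6 birds, 41 tracking days/year, 600 prey presences, 4,000
background and 4,000 null points) in a few minutes on one CPU:

```r
library(cpforage)
res <- run_pipeline(demo_config(), outdir = "demo_run", seed = 1)
str(res$summary)
```

With seed 1 this prints:

```
$ n_fixes                      : int 28044
$ n_trips                      : int 492
$ selected_scale_m             : num 1200
$ n_ars_points                 : int 9609
$ auc_mean                     : num 0.854
$ auc_sd                       : num 0.0167
$ importance                   : sst 69.6, chla 30.4, sal ~0, bathy ~0
$ deviance_explained           : num 0.956
$ fixed_effect_share           : num 0.998
$ significant_fraction         : num 0.63
```

Reading these numbers: the variance of log FPT peaks at a 1200 m radius,
close to the generator's true 1000 m ARS patch radius, so the scale
selection recovers the scale at which the simulated birds concentrate
their search. The cross-validated AUC of 0.854 ± 0.017 says a random prey
presence outscores a random background point ~85% of the time; sea
surface temperature and chlorophyll-a dominate variable importance, as
they should given the generating suitability surface. The difference
smooth (written to `demo_run/difference_smooth.csv` and plotted in
`difference_smooth.pdf`) is significantly negative early in the season
and significantly positive late with a single sign change: the simulated
birds start in poorer-than-random patches and end the season in
better-than-random ones, the qualitative signature the pipeline is built
to detect.

A shell entry point with the same stages is installed at
`inst/scripts/cpforage-pipeline.R`
(`--config cfg.yaml --seed 1 --outdir run --until infer`).

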