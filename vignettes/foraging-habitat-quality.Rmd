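---
title: "Linking central-place forager movements to prey habitat quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking central-place forager movements to prey habitat quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforage)
```

`cpforage` asks a question from optimal foraging theory: as energetic
demands rise over a breeding season, do central-place foragers improve
the quality of the patches they occupy faster than the landscape itself
improves? The package answers it by chaining four analyses — foraging
detection from GPS tracks, a prey distribution model, a resampling null
model, and a seasonal trend contrast — and ships a synthetic world with
known ground truth so the whole chain is verifiable. This vignette
documents the models, the parameters that matter, the numerical choices,
and the limits of what the synthetic tests show.

## Foraging detection: first-passage time

Animals searching a profitable patch slow down and turn more
(area-restricted search, ARS); in transit they are fast and straight.
First-passage time makes this operational: for a circle of radius $r$
centered on a track point, FPT is the time between the backward and
forward first crossings of the circle. Slow tortuous movement keeps the
animal inside the circle for a long time, so high FPT flags ARS.

Tracks are first cut into complete same-day colony round trips
(`segment_trips()`; colony radius default 500 m — the package exposes it
because no universal nest-to-beach buffer exists, and an island-scale
value is the natural default) and rediscretized to points spaced exactly
200 m *along the path* (`rediscretize()`, linear interpolation of
position and time within steps). Along-path spacing is the convention
that keeps the worked geometry consistent: on a right-angle path of two
300 m legs, the point at arc position 400 m lies on the second leg 100 m
past the corner, even though its straight-line distance to the previous
point is only ~141 m.

Crossing times use exact segment–circle intersection. Because the
distance from a fixed center to a straight segment is quasi-convex, the
first vertex at or beyond radius $r$ always brackets the true crossing,
so a quadratic solve inside that step is exact for the piecewise-linear
path model; the tests verify it against a brute-force walker that steps
the path at 1 s resolution.

The characteristic scale is selected by computing, per bird, the
variance of log FPT pooled over that bird's trip points at each radius
of a 100–5000 m grid (100 m steps, 50 candidates), averaging the
profiles across birds, and taking the radius that maximizes the average
(`select_scale()`, ties to the smallest radius). The averaging rule is a
genuine design fork — one could instead take each bird's argmax radius
and use the largest — so both are implemented behind a switch, with the
mean-profile rule as the default because it weighs every bird's full
profile rather than a single point of it. Foraging points are those in
the 90th percentile of FPT at the selected scale. The percentile
reference set is per bird by default: a per-trip reference would force
10% retention inside every trip, including pure-transit trips with no
foraging at all, which is exactly the artifact the threshold is meant to
avoid; per-trip and global references remain available as options, and a
bird with fewer than 10 defined values falls back to the pooled
distribution. Quantiles use the linear-interpolation convention.

## The prey model: regularized maximum entropy

Prey presence records (landings of commercial vessels in the motivating
system) come without absences, so the model is presence-background: find
the distribution $p_\beta(x) \propto e^{\beta^\top f(x)}$ over a
background sample that matches the presence feature means while staying
as close to uniform as possible. `maxent()` minimizes the convex
objective

$$-\tfrac{1}{n_p}\sum_{i\in\text{pres}}\beta^\top f_i
  + \log\!\sum_{b\in\text{bg}} e^{\beta^\top f_b}
  + \sum_j \pi_j\,|\beta_j|,
  \qquad \pi_j = \lambda\, s_j/\sqrt{n_p},$$

by cyclic coordinate descent with damped Newton steps, soft
thresholding, and a backtracking line search on the exact objective;
$s_j$ is the background SD of feature $j$ and $\lambda$ (default 2) is
the regularization multiplier. At $\lambda = 0$ with linear features the
fit satisfies the moment-matching optimality condition to $10^{-6}$,
and the background raw distribution always normalizes to 1 within
$10^{-9}$ — both are asserted in the tests. Features are the standard
classes (linear, quadratic, pairwise products, and two-sided hinges with
knots at background quantiles), each scaled so its background values
span $[0,1]$.

Reported suitability is the complementary log-log transform
$1 - \exp(-e^{H} p_\beta(x))$ with $H$ the entropy of the fitted
background distribution; it is strictly increasing in $p_\beta$, lies in
$(0,1)$, and equals $1 - e^{-1} \approx 0.632$ everywhere for a uniform
model — a closed form the tests pin down. Model evaluation uses 10-fold
cross-validation on the presences (`maxent_cv()`): per-fold Mann–Whitney
AUC against the background, and a final projection equal to the mean of
the fold models' cloglog outputs (matching the "averaged grid"
convention rather than averaging weights, which would not commute with
the nonlinear output). Variable importance is reported twice: percent
contribution credits each coordinate update's objective improvement to
the updated feature's parent variable (products split evenly), and
permutation importance measures the AUC drop when one variable's values
are shuffled across evaluation points, clipped at zero and normalized.

## Scoring locations and the null model

Points are annotated with environmental values by inverse-distance
weighting over the $k = 4$ nearest valid cells with power $p = 2$ (an
exact cell-center hit takes the cell value), and linear interpolation in
time between bracketing layers; the source cites IDW without parameters,
so both are exposed. Trip-level means of projected suitability are the
analysis response — averaging within trips absorbs the strong serial
autocorrelation of consecutive points. Means of exactly 0 or 1 are
compressed into the open interval with the standard
$(S(n-1)+0.5)/n$ adjustment rather than dropped.

The null model (`simulate_null_points()`) asks what habitat quality a
colony-bound bird would see "by chance": it resamples, independently and
with replacement, a timestamp, a colony bearing, and a colony distance
from the observed foraging points, and places a pseudo-point at that
polar position. Independent resampling is deliberate — it preserves each
marginal (when and how far birds ranged) while destroying the joint
structure (where they actually chose to be), which is precisely the
signal under test; a joint (row-resampling) switch exists for
sensitivity checks. Pseudo-points falling on land are redrawn (at most
100 rounds, logged), and points are grouped into per-date pseudo-trips
so both groups enter the trend model at the same (trip-mean) resolution.

## Trend inference

Trip-mean quality $S \in (0,1)$ is modeled with a beta likelihood and
logit link: parametric group (observed vs simulated; simulated is the
reference) and year terms, group-specific penalized
cubic-regression-spline smooths of Julian day (10 basis functions each),
and bird identity as a ridge-penalized random intercept, with smoothing
parameters and the beta precision chosen by REML. The fit is delegated
to `mgcv` — this is a standard penalized-likelihood additive model, and
the contract is the likelihood plus penalty, not any particular solver.
All simulated pseudo-trips share one random-intercept level; it is
shrunk toward zero like any other level, and the group contrast is
carried by the parametric term. The reported fixed-effects share of
deviance is the deviance explained by a refit without the
random-intercept block relative to the full fit — one of several
defensible partitions, and flagged as such in the summary. A common
precision $\phi$ is assumed across groups.

The seasonal contrast is the pointwise difference of the two fitted
curves: for each grid day, build the linear-predictor rows under each
group label (shared terms cancel in the difference), set
$D(d) = x_\Delta^\top \hat\beta$ and
$\mathrm{SE}(d) = \sqrt{x_\Delta^\top V x_\Delta}$ with $V$ the Bayesian
coefficient covariance, and flag days where $D \pm 1.96\,\mathrm{SE}$
excludes zero. Swapping the group labels negates $D(d)$ exactly. Under a
pure null (identical generating curves for both groups) these intervals
are conservative: the smooths are then maximally penalized, the
estimates shrink more than the covariance does, and in a 200-replicate
calibration at 400 trips per group the interval covered zero at ≥90% of
grid days in every replicate. This over-coverage is a documented
property of penalized-spline pointwise intervals in the null regime, not
an implementation artifact; users should read the significance mask as
conservative. Pairwise year differences use Wald $\chi^2$ contrasts on
the parametric year coefficients (df = 1). The individual-trait model —
logit trip quality on sex, body condition, and year with a bird random
intercept — uses `nlme`; the condition index is the per-sex standardized
residual of $\log(\text{mass})$ on $3\log(\text{tarsus})$, with perfect
allometry degrading gracefully to zero indices.

## The synthetic world

The generators define the study conditions the tests run under. The
domain is a 60 × 40 km coastal shelf at 1 km resolution with land along
the north edge and the colony on a small island; "water" is bathymetry
< 0, and foraging destinations are restricted to water. Sea surface
temperature warms at 0.09 °C/day from 27 °C on day 120, crossing the
true suitability response's steep rise between 30 and 32 °C mid-season;
chlorophyll-a is a patchy lognormal field built from six Gaussian
patches (4 km scale) in log space whose centroids drift at 150 m/day and
whose amplitude grows at 1.2%/day, so high-suitability area expands
monotonically; salinity is a smooth static estuarine-to-offshore
gradient and bathymetry a static sloping shelf. The true suitability is
a closed-form product: a logistic ramp in SST spanning the rise
interval, a linear chlorophyll response flat at and above 10 mg/m³, and
weak Gaussian optima in salinity and depth scaled to $[0.8, 1]$. Explicit
patch bumps (rather than a thresholded noise field) were chosen so patch
count, scale, and drift are directly controllable and the ground truth
is known exactly.

Birds make one round trip per tracking day: 15-minute fixes inside a
fixed 06:00–20:00 daylight window (a clock interval, not a solar
ephemeris — the tags' own daylight rule is unknown, so it is left
configurable), outbound transit at 10 m/s with small cross-track noise,
an ARS bout as a confined correlated random walk (0.8 m/s, turning-angle
SD 2 rad, confinement radius 1000 m), and return transit, with
stationary colony fixes bracketing the trip. Destinations are drawn with
probability proportional to suitability$^{\text{preference}(t)}$;
in the demo the preference exponent runs sigmoidally from −3 early (naive
fidelity to currently poor sites, producing the marked early-season
deficit relative to the null) to +3 late (strong suitability-seeking
while provisioning young). Prey presences are thinned samples with
acceptance probability equal to true suitability, so presence density is
proportional to suitability by construction. Bird masses are uniform on
2600–4330 g with tarsus following cubic allometry plus lognormal noise;
a zero-noise switch gives the exact-allometry degenerate case used to
test the condition index.

What the synthetic world does *not* emulate: GPS error and fix dropout,
tidal and current transport of prey, fish-schooling dynamics, multiple
colonies, competition or social information, and observation gaps. A
pipeline that passes these tests is verified as a correct implementation
of the methods under clean two-mode movement and a smooth dynamic prey
field — not validated against the messiness of field telemetry.

## Problem sizes and numerics

The packaged demo uses 6 birds over 41 alternate days in each of two
years (~490 trips), 600 prey presences, 4,000 background and 4,000 null
points, and a 10-basis spline per group smooth; the full-size defaults
(10,000 background and null points, every day) are one configuration
switch away. Maxent convergence is declared when a full coordinate sweep
improves the objective by less than $10^{-8}$, with a hard cap of
$10^6$ coordinate updates; ties in scale selection break to the smallest
radius; FPT is undefined (and excluded from variance pooling) where a
circle is never exited, and radii with fewer than two defined values per
bird are marked missing. Degenerate inputs fail loudly and early:
sub-2-cell grids, colonies outside the domain, zero-suitability
landscapes, empty observed point sets, and responses outside $(0,1)$ are
all rejected with messages rather than propagated.

## Known limitations

The FPT variance profile needs multi-trip, multi-mode tracks to peak
informatively; single-mode tracks give flat profiles and no defensible
scale. The difference-smooth significance mask is conservative under
weak signals (see above). Percent contribution depends on the
coordinate-descent update path (as gain-based attributions always do);
permutation importance is the path-independent complement. The
lon/lat ingest projection is a local equirectangular approximation,
adequate for single-colony extents of tens of kilometers but not for
basin-scale data.
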