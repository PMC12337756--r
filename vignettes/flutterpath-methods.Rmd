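---
title: "Methods: from butterfly GPS tracks to mixed-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from butterfly GPS tracks to mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

flutterpath analyses second-resolution GPS trajectories of butterflies
tracked afoot along a rural–urban gradient. Two groups of questions drive
the design: how *mobile* an individual is (flight speed and the shares of
time invested in stopping, nectaring and resting) and how *tortuous* its
flight path is, and how both respond to the surrounding degree of
urbanization (percent sealed soil surface) and to the local nectar supply.
Because the raw field data are a moving observer's DGPS fixes plus a
hand-kept event log of landings, most of the package is about turning that
noisy pair of records into defensible per-individual response variables;
the rest is the inference layer and a synthetic-data generator that makes
every stage testable with known ground truth.

## Stop consolidation

A landed butterfly produces not a stationary fix but a point cloud, because
the observer sways and the receiver jitters. Each annotated stop interval
`[start_s, end_s]` therefore has its member fixes (all fixes with
`start_s <= t <= end_s`) collapsed onto one representative location: the
Euclidean geometric median of the cloud, i.e. the point minimising the sum
of distances to the members — the "median center" of GIS tooling. The
median is preferred to the centroid because single wild fixes (multipath
spikes) should not drag the stop location.

Numerically the median is computed by Weiszfeld iteration started at the
centroid, with two safeguards: if an iterate lands on an input point the
standard subgradient condition decides whether that vertex is the optimum,
and after convergence (default tolerance 1e-4 m) the iterate is snapped to
a nearby input point when that point satisfies the subgradient condition —
Weiszfeld contracts slowly close to an optimal vertex, and the snap returns
the exact answer instead of a point a tolerance away.

Consolidation produces two views of a track:

* the **mobility view** keeps every retained fix, with stop members moved
  to their stop's center (so within-stop displacement is exactly zero and
  stationary jitter cannot inflate path length);
* the **tortuosity view** additionally drops all but the first adjusted fix
  of each stop, because a run of identical coordinates has no defined
  heading and would corrupt the turning-angle statistics.

Stops overlapping the first or last fix of the logging are removed from
both views entirely: such stops are artefacts of how recording starts and
ends, not behaviour. Durations for the time budgets use the span that
remains. Data-gap structure (below) is determined on the raw fix times
*before* stop thinning, so removing stop fixes never fabricates a segment
break.

## Gaps and segments

The receiver occasionally lost signal (e.g., under trees). With nominal 1-s
sampling, any inter-fix interval of `gap_threshold_s` seconds or more
(default 3 s — one missed fix is routine, two or more in a row are treated
as a hole) splits the track into segments. A hole of length Δt hides
Δt − 1 unobserved seconds. Gap intervals contribute neither distance nor
time to any metric, and tortuosity is computed per segment.

## Movement metrics

**Flight speed** is path length over the mobility view divided by flying
time: the retained span minus stop seconds minus gap seconds, accumulated
per segment. The alternative — dividing by total duration — would conflate
speed with the stopping share, which the models treat as a separate
response; a `definition = "gross"` switch provides it for comparison. A
stop interval `[s, e]` occupies the unit seconds `s .. e-1`, which makes
the budget shares exactly the per-second classification of the event log.

**Time budgets** are the shares of the retained span spent stopping (all
stop activities, including basking, oviposition and unlabelled stops),
nectaring, and resting. Nectaring + resting can never exceed stopping.

**Tortuosity** is Benhamou's corrected sinuosity,

$$\mathrm{Sin} = 2\,\bigl[p\,\bigl(\tfrac{1+c}{1-c} + b^2\bigr)\bigr]^{-1/2},$$

with `p` the mean step length (m), `c` the mean cosine of the turning
angles and `b` the coefficient of variation of step length (population SD
by convention, fixed for determinism; the difference from the sample SD is
negligible at track scale). The index is the one computed by trajr's
`TrajSinuosity2`; its units are m^(-1/2), and uniformly rescaling
coordinates by k rescales it by k^(-1/2) — a property the tests exercise.
A perfectly straight path (`c = 1`) is assigned 0 by continuity. Exact
duplicate fixes are merged before angles are computed, since a zero-length
step has no heading. Per-track sinuosity is the weighted mean over
segments, weighted by segment path length ("track segment length" read as
metric length; a duration-weighting switch exists because the reading is
genuinely ambiguous). Segments with fewer than 3 distinct fixes admit no
turning angle and are dropped with a warning.

## Environmental covariates

* **Nectar coverage** is the arithmetic mean of per-1-m-segment percent
  covers of a transect through the movement area.
* **Urbanization** is mean percent sealed surface within a circular buffer
  of 500, 1000 and 2000 m around the site center, computed on a 2 × 2 m
  grid. Cell membership is by cell center: at ≥ 500-m radii and 2-m cells
  the discretisation error is below 0.1%, and the rule is deterministic —
  fractional-area weighting would buy nothing measurable.
* Where the sealing map covers only part of the region, missing cells are
  imputed with the mean sealing of their biotope class, the class means
  being estimated where both maps overlap. The operation is the identity
  on fully covered rasters and idempotent.
* **Habitat area** is the shoelace area of the digitised habitat polygon
  (holes subtracted), in hectares. Self-intersecting rings are rejected.

Rasters travel as ESRI ASCII grids and vector data as GeoJSON — plain-text
formats the package reads and writes itself.

Geographic input coordinates are projected to a local transverse Mercator
centred on the track centroid, evaluated on the prime-vertical sphere with
latitude differences rescaled by the meridional/prime-vertical curvature
ratio. Over sub-kilometre track extents this tracks WGS84 geodesic
distances to well under 0.1% (verified against an independent geodesic
oracle); absolute coordinates are not reproducible across tools — only
relative geometry matters here.

## Inference

Numeric predictors are centred and scaled to unit SD, so coefficients are
comparable across predictors; the constants are kept for
back-transformation. Predictors are screened for collinearity with pairwise
Spearman correlations at the conventional |rs| ≥ 0.5 threshold; the
pipeline proposes dropping the member of a flagged pair with the larger
mean absolute correlation, but the user decides.

Responses live on the open unit interval (beta family, logit link) or the
positive half-line (lognormal family, log link). Shares that can be exactly
0 get a 1e-10 additive constant; speeds and sinuosities are divided by 10
to fit inside the unit interval; values still at 1 are nudged to 1 − 1e-6
with a warning, since beta support is open.

Each model carries three random intercepts: site, habitat area and track
duration. Treating the two continuous variables as grouping factors — every
distinct value is a level — is a faithful rendition of how the original
analysis handed them to the mixed-model machinery; it is unusual (the
duration factor is nearly one level per individual and its variance is
often estimated at zero or absorbs residual heterogeneity), so a
`random_as_fixed` switch enters them as fixed covariates instead. Fits are
maximum likelihood via glmmTMB; the package's own contracts are the
transformation rules, factor construction, Wald tables (z = coef/SE,
two-sided normal p), diagnostics, and selection logic. Singular
random-effect variances are reported as ≈ 0 and flagged, not treated as
errors. No multiple-testing correction is applied — per-coefficient Wald
p-values are reported as-is, matching the original analysis; readers should
weigh the number of tests themselves.

**Residual diagnostics** are simulation-based randomized-quantile checks:
`n_sim ≥ 250` response sets are simulated from the fitted model and each
observation's randomized rank among its simulations is computed — uniform
on (0, 1) under a correctly specified model. Uniformity is measured by the
Kolmogorov–Smirnov distance, but its p-value comes from a Monte-Carlo
null rather than the textbook KS reference: every simulated response set
is scored exactly like the observed one within the pooled set, and the
observed distance is ranked among the simulated distances. The reason is
dependence — the simulations redraw the random effects, so residuals are
correlated within grouping levels, and against the iid-uniform KS
reference that correlation inflates the rejection rate (we measured ~12%
at a nominal 5%); the exchangeable Monte-Carlo null is calibrated by
construction. Dispersion is a two-sided Monte-Carlo test of the observed
residual variance among the simulated ones, residuals taken about the
simulation-based expectation (the conditional fitted values are not a
fair center when simulations redraw the random effects).

Two further design points deserve note. First, calibration is assessed by
drawing *fresh* responses from a fitted model and scoring them against
that same fit: the ranks are then exactly uniform by exchangeability, and
the rejection rate sits at the nominal level. Refitting to every
replicate makes such diagnostics conservative (rejection well below
nominal) — a property of simulation diagnostics generally, not of this
implementation. Second, power against overdispersion is demonstrated by
inflating the residuals of the observations relative to an
already-fitted model (the `observed` argument): a beta model refitted to
noisier beta data would simply re-estimate its free precision parameter
and show nothing.

**Buffer-radius selection** fits the roster at each candidate radius and
takes the radius with the lowest (total) AIC, ties going to the larger
radius — the original analysis reports only that one radius "best
explained" the responses without naming a criterion, and AIC is the
conventional choice.

Species-level descriptive contrasts use the two-sided Wilcoxon rank sum
test: exact when both samples have at most 10 untied values, otherwise the
normal approximation with tie-corrected variance and no continuity
correction (so identical samples give p = 1).

## The synthetic generators

`simulate_track()` emulates the statistical structure the estimators
assume: headings evolve by von Mises(0, κ) increments (chosen because the
mean turning-angle cosine has the closed form I₁(κ)/I₀(κ), giving an
analytic sinuosity target), step lengths are gamma with mean `p` and CV
`b` at one step per second, stop bouts freeze the true position and emit
jittered fixes plus an event-log row, and interior fixes are deleted with a
small probability to emulate signal loss. Stops never touch the first or
last fix, so the generated event log's time budget is exactly recoverable —
which is what the exactness tests assert. Defaults are the study
conditions: ~300 flight seconds (observed duration 336 ± 158 s), mean step
0.8 m (between the two species' mean speeds of 0.63 and 0.98 m/s), step CV
0.5, heading persistence c = 0.6 (giving sinuosity near the observed ~1.1),
1.5 stops per flight minute of mean length 20 s, 5 cm stationary jitter
(observer sway dominates the 2 cm receiver accuracy), 1% per-second fix
loss. These were chosen once from the study's reported summaries and are
not tuned.

`simulate_study()` draws a full per-individual table from the stated beta
or lognormal mixed model — 29 sites (urbanization 31.9 ± 17.7%), five
individuals per site, nectar coverage 9.2 ± 8.3%, with known logit/log-scale
coefficients and random-intercept SDs — in exactly the schema of
`summaries.csv`/`covariates.csv`, so the inference stage is validated by
parameter recovery rather than by eyeballing. `simulate_transect()` and
`simulate_landscape()` play the same role for the covariate operations,
recording their generating class means and gradients.

What the generators deliberately do **not** emulate: observer lag behind
the butterfly, spatially autocorrelated resource fields, mechanistic
foraging (perception, taxis), or heavy-tailed step distributions. Passing
tests therefore show that the estimators recover the truth *under the
model the analysis assumes*, not that the field data satisfy that model.

## Problem sizes and numerical choices

The validation suite uses 500 correlated-random-walk tracks of 200 steps
for estimator consistency (the mean estimate must sit within ±3 standard
errors of the closed form), 50 random point clouds against a millimetre
grid-search oracle (valid because the objective is convex), 100 random
tracks for time-budget exactness, 200 replicates of n = 600 individuals
for coefficient recovery (±0.02 on true effects of ±0.15), 400 null
replicates of n = 300 for Wald type-I error (accepted in [0.03, 0.08]),
400 fresh-draw replicates for KS calibration and 50 for dispersion power.
The acceptance script recomputes the same quantities at somewhat smaller
replicate counts suited to a single-CPU run; sizes are stated in its
output. Remaining numerical conventions: Weiszfeld tolerance 1e-4 m with
vertex snapping; gap threshold 3 s; minimum 3 distinct fixes per sinuosity
segment; beta responses nudged to 1 − 1e-6; population SD in `b`; all
randomness flows from explicit seeds and every generator is a pure
function of (config, seed).

## Known limitations

* The observer's path is a proxy for the butterfly's; speeds and
  sinuosities inherit that bias and nothing in the package can remove it.
* The continuous-grouping random intercepts are kept for fidelity, not
  because they are statistically attractive; use `random_as_fixed = TRUE`
  for the conventional specification and compare.
* Stop detection relies entirely on the field event log; there is no
  unsupervised stop inference from positional variance.
* A stop straddling a data gap is treated as two member sets sharing one
  consolidated center.
* Reproducing the published coefficient tables requires the archived
  per-individual dataset; without it the reproduction harness runs on
  synthetic tables of the same shape.
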