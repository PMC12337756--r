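# flutterpath

Movement analysis of GPS-tracked butterflies along a rural–urban gradient.

Butterflies are small enough that their movements are recorded indirectly:
an observer follows the animal afoot with a high-accuracy DGPS receiver at
1-s resolution and keeps an event log of every landing (nectaring, resting,
basking, oviposition). flutterpath turns that pair of records into
per-individual response variables and fits the mixed-effect models that ask
how butterfly mobility and flight-path tortuosity respond to urbanization
(percent sealed surface around the site) and to nectar-plant supply.

The pipeline:

1. **Stop consolidation** — each annotated stop's GPS point cloud is
   collapsed onto its geometric median (Weiszfeld iteration with vertex
   handling); stops overlapping the start or end of logging are excluded.
   Two views result: a *mobility* view (all fixes, stop members moved to
   the stop center) and a *tortuosity* view (only the first adjusted fix
   of each stop retained).
2. **Movement metrics** — mean flight speed (path length over flying time,
   stop and gap seconds excluded), time-budget shares (stopping, nectaring,
   resting), and Benhamou's corrected sinuosity

   Sin = 2 [ p ( (1+c)/(1−c) + b² ) ]^(−1/2)

   with p the mean step length, c the mean cosine of turning angles and b
   the step-length coefficient of variation, computed per gap-free segment
   and averaged with path-length weights.
3. **Covariates** — mean nectar coverage over 1-m transect segments,
   biotope-class imputation of partially observed sealing rasters, zonal
   mean sealing in 500/1000/2000-m buffers, habitat area in hectares.
4. **Inference** — scaled predictors, Spearman collinearity screen
   (|rs| ≥ 0.5), beta (logit) / lognormal (log) GLMMs with random
   intercepts for site, habitat area and track duration (glmmTMB backend),
   Wald tables, simulation-based uniformity/dispersion residual
   diagnostics, AIC-based buffer-radius selection, and Wilcoxon rank-sum
   species contrasts.
5. **Synthetic data** — correlated-random-walk tracks (von Mises turns,
   gamma steps) with stop bouts and GPS jitter, transects, landscapes and
   a full study simulator with known coefficients, so every stage is
   verifiable without field data.

## Worked example

Simulate a five-minute track with stop bouts, consolidate it against its
event log and derive the per-individual summary row:

```r
library(flutterpath)

cfg <- track_sim_config(n_steps = 300, seed = 42)
sim <- simulate_track(cfg)
pt  <- consolidate(sim$trajectory, sim$events, gap_threshold_s = 3)
pt
#> <fp_processed_track> sim1: 407 mobility fixes, 301 tortuosity fixes, 5 stop(s), 1 segment(s)
print(movement_summary(pt), digits = 3)
#>   individual_id species     sex site_id duration_s path_m flight_speed stopping
#> 1          sim1      CP unknown   site1        407    246        0.821    0.263
#>   nectaring resting sinuosity n_stops n_segments
#> 1     0.108   0.155      1.05       5          1
sim$truth[c("speed", "sinuosity", "stopping_share")]
#> speed 0.821 m/s, sinuosity 1.085, stopping share 0.263
```

The flight speed (0.821 m/s) and stopping share (0.263) recover the
generating truth exactly up to Monte-Carlo error in the steps, and the
estimated sinuosity (1.05) sits near the generating closed form (1.085).

Fit a beta mixed model of flight speed on scaled nectar coverage and
urbanization for a simulated study of 29 sites and inspect the residual
diagnostics:

```r
s   <- simulate_study(study_sim_config(
  n_sites = 29, n_per_site = 5,
  true_coefs = c(intercept = -1, np_cov = -0.15, urbanization = 0.15),
  seed = 7))
tab <- scale_predictors(s$table, c("np_cov", "urbanization_2000"))
tab$speed10 <- transform_response(tab$flight_speed, divide_by_10 = TRUE)
fit <- fit_glmm(tab, "speed10", c("np_cov", "urbanization_2000"),
                family = "beta_logit")
fit
#> <fp_model_fit> speed10 ~ np_cov + urbanization_2000  [beta_logit], n=145, AIC=-278.8
#>                term estimate std_error      z        p
#> 1       (Intercept)  -1.0241    0.0625 -16.39 2.25e-60
#> 2            np_cov  -0.1712    0.0388  -4.42 9.91e-06
#> 3 urbanization_2000   0.0909    0.0622   1.46 1.44e-01
residual_diagnostics(fit, n_sim = 250, seed = 1)
#> KS uniformity p = 0.977, dispersion p = 0.853 -> ok
```

A single replicate of 145 individuals recovers the generating effects
(−0.15 and +0.15) within its standard errors; across 200 replicates of
n = 600 the mean estimates land within ±0.02 (see the test suite).

`reproduce_models()` runs the whole inference stage (scaling, screen,
radius selection, ten response×species models, diagnostics) on any
per-individual table in the archived-data shape, and `run_pipeline()`
orchestrates the full track-to-models flow from files. A thin CLI wrapper
lives at `inst/cli/flutterpath.R`.

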