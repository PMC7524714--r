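# pelvisop

Measure the **sagittal orientation of the pelvis (SOP)** from biplanar
orthogonal radiograph-like projections, evaluate the measurement with a
controlled phantom protocol, predict the **postoperative standing SOP**
after total hip arthroplasty (THA) from preoperative parameters by LASSO
model selection, and quantify how pelvic-tilt uncertainty shrinks a
range-of-motion cup **safe zone**.

The package is aimed at researchers in orthopaedic biomechanics and surgical
planning who need a tested, fully synthetic re-implementation of this
analysis chain: no patient data are required — a synthetic-data module
generates a landmarked template pelvis, phantom views and patient cohorts
whose marginals and generating models follow the published cohort tables.

## The methods in brief

**Measurement.** A pelvis model (named 3D landmarks, optionally a silhouette
point cloud) is rigidly registered to two orthographic projections — an AP
view (x, z) and a lateral view (y, z) sharing the vertical axis — by
least-squares fitting of four picked landmarks (hip centres, pubic
symphysis, sacral promontory), optionally refined on projected contours. The
solved pose is decomposed in the fixed sequence transverse Z → sagittal X →
frontal Y, so the SOP is adjusted for the axial and frontal orientation;
positive SOP is anterior tilt. Five landmark-defined reference planes (SSP,
PTP, APP and two configurable slots) provide the plane-specific SOP
readings; pose-invariant morphology (pelvic incidence, 13 landmark
distances, 5 landmark angles) and the lumbar lordosis angle (L1–S1, L1–L5
when fused) complete the parametrisation.

**Prediction.** For a cohort with 31 (scenario A: supine CT only) or 33
(scenario B: plus standing imaging) preoperative predictors, the
postoperative standing SOP is modelled by L1-penalised linear regression
(coordinate descent, compiled) with exact leave-one-out cross-validation.
Four models are compared — `max`, `minMSE`, `oneSE` (one-standard-error
rule), `min` (single predictor) — by likelihood-ratio tests and ΔAIC/ΔBIC,
with post-selection OLS refits supplying estimates, SEs and p-values,
e.g. scenario B:

```
postop_standing_sop = -4.59 + 0.09*LLA + 0.31*supine_SOP + 0.61*standing_SOP + e,  sd(e) = 3.6
```

**Safe zone.** A cup orientation (radiographic inclination/anteversion, APP
frame) is impingement-free if the prosthetic neck stays inside the free cone
of half the oscillation angle `180° − 2 asin(neck/head)` through a required
range of motion; intersecting the zones over a set of plausible sagittal
tilt offsets gives the shrinkage the tilt uncertainty costs.

## Worked example

```r
library(pelvisop)

## measure the SOP of a posed pelvis from synthetic biplanar views
tp <- template_pelvis()                       # designed sacral slope 38.5 deg
v  <- generate_phantom_views(tp, d_sop = 10,  # anterior tilt of +10 deg
                             pick_noise_sd = 0.5, seed = 42)
measure_sop(tp, v, "SSP")[1:3]
#>   sop   fop   top
#> 48.59  0.04  0.33
```

The sacral-slope-plane SOP comes back as 48.59 degrees: the designed sacral
slope (38.5) plus the applied 10-degree anterior tilt, off by 0.09 degrees
due to the 0.5 mm landmark-pick noise.

```r
## predict the postoperative standing SOP on a synthetic scenario-B cohort
coh <- generate_cohort(generator_config(n = 1000, scenario = "B", seed = 42))
fit <- fit_sop_models(coh, "B")
fit
#>        NoP RMSE R2_adj
#> max     32 3.67  0.852
#> minMSE  11 3.60  0.854
#> oneSE    3 3.61  0.851
#> min      1 3.91  0.826
#>
#> oneSE model predictors: supine_sop, standing_sop, lla

summary(fit)
#> scenario B, oneSE model (n = 1000)
#>              Estimate Std. Error t value Pr(>|t|)
#> (Intercept)   -4.0262     0.7725   -5.21  2.3e-07 ***
#> supine_sop     0.2985     0.0255   11.72  < 2e-16 ***
#> standing_sop   0.6202     0.0215   28.86  < 2e-16 ***
#> lla            0.0754     0.0116    6.52  1.1e-10 ***
#> LOOCV RMSE 3.61 deg, adjusted R^2 0.851
#> min vs oneSE: LRT = 162.33 (df 2, p = 5.64e-36), dAIC = 158.3, ...
```

The one-standard-error model recovers exactly the three generating
predictors with coefficients near their generating values (0.31, 0.61,
0.09), a cross-validated RMSE matching the generator's 3.6-degree residual
SD, and very strong support over the single-predictor model — the same
qualitative structure as the published scenario-B analysis.

```r
## safe-zone shrinkage under SOP-change uncertainty of -3 +/- k*4 deg
z <- rom_safe_zone(prosthesis_spec(32, 11.5, 130, 15), grid_step = 1)
sapply(c(4, 8, 12), function(w)
  shrink_for_uncertainty(z, c(-3 - w, -3, -3 + w, 0))$reduction_percent)
#> [1] 21.0 37.2 49.6   # strictly growing with the uncertainty width
```

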