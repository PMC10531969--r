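# plateaugap

Quantification of articular fracture displacement in tibial plateau
fractures, in three dimensions, and its association with patient-reported
functional outcome.

## The problem

Tibial plateau fractures disrupt the articular surface of the knee.
Displacement is conventionally measured as a maximal gap and step-off on a
single CT slice, a procedure with poor interobserver reliability that
underestimates the true incongruity. The 3D alternative implemented here is
the **3D gap area**: delineate the articular surface on each fracture
fragment, extract the fracture lines from the contours of those articular
patches, span all fracture lines with a triangulated surface, and report
that surface's area in mm². The measure captures gaps, step-offs and
combined displacement in every plane at once:

* *initial* displacement is measured on the preoperative fragment model;
* *residual* displacement is measured on the same preoperative fragments
  after rigidly repositioning each one onto the postoperative model with
  surface-based matching (trimmed point-to-plane ICP), so implant artefacts
  in the postoperative scan never contaminate the measurement.

Cases are stratified into prognostic groups by gap area — excellent
(0–150 mm²), good (151–550 mm²), moderate (551–1000 mm²), poor
(>1000 mm²) — and related to the Knee injury and Osteoarthritis Outcome
Score (KOOS; five subscales scored 0–100). The association is estimated by
multiple linear regression of each subscale on the gap area per 100 mm²,
adjusted for age, sex, BMI, smoking, AO/OTA class, complications,
radiographic reduction quality and follow-up time:

```
KOOS_s = b0 + B_s * (gap area / 100 mm²) + confounders + error
```

The package covers the full chain — mesh IO (STL/PLY), articular
delineation (per-vertex annotations or a normal-plus-height heuristic),
fracture-line extraction, gap-surface construction, fragment matching,
radiographic reduction parameters (articular gap/step-off, MPTA, PPTA),
KOOS scoring with total-knee-arthroplasty imputation, cohort statistics —
plus a synthetic-data module that generates fractured plateau meshes with
analytic and numeric gap-area oracles and simulated cohorts with known
regression coefficients, so every stage is testable without patient data.

## Worked example

A synthetic plateau split along a diameter, the upper fragment displaced
5 mm perpendicular to the cut; the analytic gap area is 2·R·w = 300 mm²:

```r
library(plateaugap)

sc  <- fracture_scenario(cut_angles = c(0, 180),
         displacements = list(list(translation = c(0, -5, 0)),
                              list(translation = c(0, 0, 0))))
syn <- fracture_and_displace(sc)
quantify_gap(syn$case)
#> <gap_quantification> 3D gap area 300.4 mm^2 ( good ), 1 loop(s)

# a postoperative model with 80% of the displacement reduced
post <- make_postop_model(syn, lambda = 0.8)
m    <- match_fragments(syn$case, post$mesh)
m
#> <match_result> 2 fragment(s)
#>   frag01: rms 0.0000 mm, inliers 1.00
#>   frag02: rms 0.0000 mm, inliers 1.00
res <- residual_gap_area(syn$case, m)
round(as.numeric(res), 1)          # 60.1 mm^2 -> "excellent"
```

The measured 300.4 mm² sits within 0.2% of the analytic value (the extra
0.4 mm² comes from the mildly curved articular surface); after matching,
the residual gap equals the 20% of displacement left in place.

A simulated cohort with the published covariate structure, scored and fit
with the eight-confounder model:

```r
co  <- simulate_cohort(cohort_spec(n = 362, seed = 1))
fit_ols(co, "symptoms", "initial_gap_mm2")
#> <regression_result> symptoms ~ initial_gap_mm2 (n = 362)
#>   gap area (per 100 mm^2): B = -0.8 (-1.1 to -0.5), p = 1.33e-06
table(assign_prognostic_group(co$initial_gap_mm2))
#> excellent      good  moderate      poor
#>        57       158        65        82
```

The fitted B means: every additional 100 mm² of initial gap area costs
about 0.8 KOOS-symptoms points at follow-up, confounders held fixed.

## Layout

* `R/` — implementation: mesh IO and geometry, articular delineation,
  gap quantification, registration, radiographic parameters, KOOS,
  cohort statistics, synthetic data.
* `src/` — minimal-area polygon triangulation (Rcpp).
* `tests/testthat/` — unit, property and acceptance suites.
* `vignettes/gap-area-methods.Rmd` — the methods vignette: model,
  parameters, numerical choices, generator design, limitations.
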