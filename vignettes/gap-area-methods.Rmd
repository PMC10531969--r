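---
title: "Measuring tibial plateau fracture displacement as a 3D gap area"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tibial plateau fracture displacement as a 3D gap area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateaugap)
```

## The measurement model

A tibial plateau fracture separates the proximal tibial articular surface
into fragments. The quantity this package computes, the **3D gap area**, is
the area (mm²) of a triangulated surface spanning all fracture lines at the
articular level. Where the conventional 2D approach reads a single maximal
gap and step-off from one CT slice, the 3D gap area integrates the
separation between all fragment margins in all planes: a pure in-plane gap
of width $w$ along a fracture line of length $L$ contributes $\approx Lw$;
a pure depression (step-off) of depth $d$ contributes the vertical band
$\approx Ld$; combined and rotational displacements contribute the area of
the ruled surface between the displaced margins.

The measurement assumes that fragment meshes are given in a common
coordinate frame in millimetres, already segmented (CT segmentation is
upstream of this package), and that the articular surface of each fragment
can be identified — either by per-vertex annotations produced by an
operator, or by the geometric heuristic below.

The same measurement applied twice gives the two clinical quantities:
on the preoperative fragment configuration it is the *initial*
displacement; on the preoperative fragments rigidly repositioned onto the
postoperative model it is the *residual* displacement. Residual
displacement is deliberately never measured on the postoperative mesh
itself: postoperative scans carry implant artefacts, so the preoperative
fragment geometry is the measurement substrate and only the fragment
*poses* come from the postoperative scan.

## Pipeline and parameters

`quantify_gap()` composes five stages. All parameters below are recorded in
the result's provenance block.

**Plateau frame.** The proximal axis is the principal direction of smallest
variance of the articular-candidate vertices, oriented along the mean
articular vertex normal; the medial axis is the in-plane direction of
largest variance with its sign fixed by the third central moment (plateaus
are wider medially), and the anterior axis completes a right-handed frame.
All 2D footprint operations project onto the plane orthogonal to the
proximal axis.

**Articular delineation.** The annotation method uses the stored mask
verbatim and is the primary path — it keeps the measurement faithful to an
operator's judgement and makes the pipeline deterministic. The heuristic
fallback selects vertices that have a proximally facing incident face
(within `theta_deg = 45`° of the proximal axis) and lie above the
`height_q = 0.25` height quantile of the fragment (discarding the shaft
side), then keeps the largest connected component. The face-based normal
test (rather than averaged vertex normals) keeps the articular rim ring,
whose vertex normals straddle the 45° limit between top and wall faces.

**Rim vs fracture classification.** The fracture lines are the parts of
each articular patch boundary created by the fracture, as opposed to the
native joint rim. The package computes the outer footprint of all patches
projected into the plateau plane as an alpha shape (`alpha = 15` mm, via
the 2D Delaunay triangulation; convex-hull fallback with a warning) and
labels a boundary edge *rim* when its projected midpoint lies within
`delta = 2` mm of the footprint boundary **and** the edge runs within 45°
of the local boundary tangent. The tangent condition matters: fracture
lines meet the rim nearly perpendicularly, and without it the last
`delta` millimetres of every fracture line would be swallowed by the rim
band, truncating the gap surface by several percent. Two post-processing
rules follow from the footprint construction: fracture edges are chained
per fragment and split at turns sharper than 45° (so corridors meeting at
a junction, e.g. the apex of a Y-shaped fracture, become separate lines),
and short pieces (< 5 mm, and under half the length of their chain's main
piece) hanging off a chain at such a corner are relabeled rim — they are
rim edges that fell outside the rim band because an alpha shape cannot
follow the footprint into the mouth of a gap corridor.

**Stitching.** Fracture-line endpoints from different fragments are paired
greedily into closed loops. A pair is admissible when its distance is at
most `max(join_tol, 2 ×` the endpoint's distance to the nearest
cross-fragment endpoint`)`, with `join_tol = 1` mm — the admissible radius
scales with the local gap width. Greedy order is by endpoint distance plus
half the symmetric chamfer distance between the two chains, which makes
chains bordering the *same* corridor pair up at multi-fragment junctions
where several endpoints cluster. Ties break deterministically by fragment
id and point index. Chains left open are closed onto themselves with a
warning and discarded when the folded loop spans under 1 mm².

**Triangulation.** Each loop is triangulated by the minimal-total-area
triangulation over its own vertices (dynamic programming over chords,
$O(n^3)$, implemented in C++). This rule is exact for planar convex loops,
selects the smaller diagonal of a skew quadrilateral, and reproduces ruled
surfaces between densely sampled margins; it is deterministic and needs no
plane projection, which keeps the measure rigid-motion invariant (the
suite checks invariance to 0.1%). Collinear loops give zero area without
error. A constrained-Delaunay interior triangulation was considered and
rejected: it requires a projection plane (ill-defined for strongly folded
loops) and an interior-point lifting rule, and on band-shaped gap loops it
changes the area by less than the minimal triangulation's own
discretization error.

## Surface-based matching

`match_fragments()` is a two-level registration. The coarse stage aligns
centroid and principal axes of the largest (shaft-bearing) fragment to the
postoperative model; the four sign combinations that keep a proper
rotation are each refined by a short trimmed ICP and scored by the
symmetric sampled chamfer distance of the whole case, which resolves the
near-symmetry of a plateau-shaped object. The fine stage registers each
fragment independently with trimmed point-to-plane ICP: correspondences
are nearest postoperative vertices; pairs farther than `cutoff = 3` mm —
the trimming radius starts at `1.5 ×` the median correspondence distance
and tightens to the cutoff — or with normals more than 60° apart are
discarded. Normal gating is essential near a narrow, almost-reduced gap:
without it, points on one side latch onto the opposing wall of the
neighbouring fragment and bias the pose. Fragments with fewer than 200
vertices inherit the global transform and are flagged (small rim fragments
register unstably), as are fragments whose inlier fraction ends below 0.5.
Fewer than 50 correspondences within the cutoff at initialization is a
registration failure. Sampling is an evenly spaced vertex subsample, so
the whole procedure is deterministic.

## Outcome scoring and cohort statistics

KOOS answers (42 items, 0–4) are scored per subscale as
$100 - 25\,\overline{a}$ with the standard half-rule: a subscale is
missing unless at least 50% of its items are answered, and the mean runs
over answered items. Patients converted to total knee arthroplasty receive
fixed subscale values (symptoms 52, pain 45, ADL 55, sport 16, QoL 27)
representing their state just before conversion, overriding any completed
questionnaire.

Gap areas map to prognostic groups by upper-inclusive intervals
$[0,150]$, $(150,550]$, $(550,1000]$, $(1000,\infty)$ mm² — the
exhaustive continuum partition consistent with the integer-labeled bins
they are reported under. Group differences use the classical one-way
ANOVA F test (defined as $F=0$ when there is no between-group variation).
The adjusted association uses OLS with the gap area per 100 mm² and the
confounders age, sex, BMI, smoking, AO/OTA class (dummy-coded against
41-B1), complication, follow-up time, and — in the initial-displacement
model only — inadequate radiographic reduction; the residual model omits
it because the residual gap area itself measures reduction quality.
Reference levels are male, non-smoker, no complication, adequate
reduction. Analysis is complete-case; confidence intervals are t-based at
95%; a rank-deficient design is an error naming the collinear terms.
Radiographic reduction is classified anatomical when gap and step-off are
both ≤ 2 mm, MPTA lies in 87 ± 5° and PPTA in 9 ± 5° (closed intervals:
the phrasing of the thresholds gives no strictness, so boundary values
count as anatomical). Nonresponse checks use a Welch t test from summary
statistics and a two-proportion chi-square with continuity correction.

## The synthetic-data generator

The generator exists so that every stage has ground truth. It emulates two
things; everything else about real data it deliberately does not model.

**Fracture meshes.** The plateau is a watertight slab: a mildly concave
bicondylar top (two Gaussian dishes of depth 1.2 mm), a 0.08 posterior
slope, a rim radius modulated as
$R\,(1 + 0.10\cos\theta + 0.05\sin 2\theta)$ (wider medially, as a real
plateau is), an outer wall, and a short shaft stub. The two asymmetries
are not cosmetic: a perfectly circular slab is invariant under a 180°
rotation, which makes surface-based alignment ill-posed — no registration
method could recover a pose the geometry does not determine. Both are
arranged to leave the canonical oracles intact: the rim modulation cancels
on opposite rays, and the slope vanishes along the x-axis, so a diameter
cut retains total length $2R$ and the flat-top closed forms hold — pure
separation $w$ gives $2Rw$, pure depression $d$ gives $2Rd$ (the mild top
curvature adds ≲ 0.2%). Fractures are radial sector partitions with known
per-fragment rigid displacements; each fragment is meshed directly from
the shared height field, so cut faces match exactly and the generator
knows every fracture edge. The general oracle integrates the ruled surface
between the two displaced copies of each cut line at 0.1 mm sampling.
Postoperative models move each fragment a fraction $\lambda$ back toward
its intact pose and merge the fragments into one unlabeled composite,
returning the true preop→postop transforms for registration oracles.

What the meshes do *not* emulate: real condylar anatomy, comminution with
free osteochondral bodies, segmentation noise, partial articular capture,
or curved fracture surfaces. Passing the oracle suite therefore
demonstrates that the measurement chain is correct on clean geometry with
known truth — not that delineation heuristics or registration are robust
to segmentation artefacts.

**Cohorts.** Covariates follow the published cohort structure: age
N(52, 14) truncated to 18–90, 69% women, BMI N(26.2, 4.7), 23% smokers,
AO/OTA multinomial (5/16/54/6/3/16%), follow-up N(7.0, 3.7 years)
truncated positive, 11% complications, 14% TKA conversions. Gap areas are
log-normal: the initial-displacement parameters (meanlog 6.14,
sdlog 1.10) solve the two-quantile equations matching the reported
excellent/good group boundaries of the 55/148/72/87 split, and the
residual parameters (meanlog 5.90, sdlog 0.79) are the least-squares
probit fit to the reported 11/31/25/5 split. Both are truncated at
3000 mm², the upper end of the reported range. Scores are generated as
`intercept + b_gap · gap/100 + confounder effects + N(0, sd)`, clamped to
[0, 100]; the per-subscale `b_gap` defaults are the published
per-100-mm² coefficients (initial model: −0.9, −0.9, −0.8, −1.4, −1.1
for symptoms, pain, ADL, sport, QoL; residual model: −2.2, −2.4, −2.2,
−2.6, −2.4), noise defaults to SD 18 and confounder effects to zero.

Two generator defaults came from an explicit design analysis rather than
from the published tables, and are worth recording. First, the 3000 mm²
truncation: with an unbounded log-normal, the heavy right tail places high-
leverage observations deep in the floor of the 0–100 scale, and clamping
then attenuates a recovered gap coefficient by 0.2–0.6 points — enough to
defeat any recovery study. Second, the intercept defaults sit mid-range
(symptoms 70, pain 70, ADL 72, sport 60, QoL 65): with the linear
predictor interior to the scale over the observed gap range, the
clamping-induced attenuation drops to ~0.01–0.05 points, an order of
magnitude below the Monte-Carlo standard error of the recovery
simulations, and 95% confidence intervals retain nominal coverage. The
price is realism at the top of the scale: real KOOS data show ceiling
effects in mildly injured patients that these defaults deliberately do not
reproduce. Recovery simulations also set the TKA probability to zero,
because the imputation replaces model-generated scores with constants that
are not part of the linear model being recovered.

## Numerical choices and degenerate inputs

Mesh loading merges vertices within 10⁻⁶ mm and drops degenerate
triangles, making loading deterministic; fragment meshes must be
edge-manifold afterwards (boundary edges allowed). Footprint points are
thinned on a 0.3 mm grid before Delaunay triangulation. Rotations are kept
proper by SVD projection after composition. Degenerate inputs fail loudly
and early: empty articular selections, landmark points that coincide,
negative gap areas, non-TKA records passed to the imputation, cohorts with
a constant predictor. An intact plateau yields zero fracture lines and a
gap area of exactly 0; a single unmatched fracture line yields an empty
loop set with a warning, not a spurious area.

Problem sizes in the test-suite were chosen to keep the full run around a
minute: synthetic plateaus use 20 radial × 80 angular subdivisions
(≈ 3700 vertices per case; the articular-area estimate changes by < 1%
when resolution doubles), recovery studies use 50 replicates at the
published cohort sizes (n = 362 initial, n = 72 residual) with 500
replicates for the coverage check, and the ANOVA null study uses 1000
replicates at the published group sizes.

## Known limitations

* The rim/fracture separation depends on the footprint alpha shape; for
  gap corridors wider than the alpha radius (15 mm) the footprint would
  split and the corridor mouth would be misread. Displacements of that
  magnitude are far outside the clinically observed range.
* Gap loops are spanned across their own vertices only; a gap surface
  that should be strongly curved between margins (e.g. wrapping a
  depressed fragment that rotated by tens of degrees) is measured as its
  ruled/minimal counterpart.
* Registration assumes the postoperative model contains most of each
  fragment's surface; fragments missing from the model are flagged, not
  recovered.
* The cohort generator's outcome model is linear with homoscedastic
  Gaussian noise; it supports parameter-recovery studies, not realistic
  score distributions (no ceiling effects, no item-level simulation).
* The eligibility cascade applies exclusions in a fixed published order;
  for records carrying several flags the per-step counts (not the final
  eligible number) depend on that order.
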