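---
title: "Interobserver contouring agreement and dosimetric variability for a geometric heart atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interobserver contouring agreement and dosimetric variability for a geometric heart atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardatlas)
```

## The problem

Retrospective epidemiologic studies of late cardiac effects after breast
radiotherapy need per-structure heart doses, but the CT imaging available for
patients treated decades ago is coarse (slices up to 10 mm, no contrast), so
small anatomical structures cannot be contoured reliably. A pragmatic answer
is a *geometric* heart atlas: the complete heart is contoured, and the
substructures of interest are simple surrogate volumes — a cone at the aortic
root for the aortic valve, a sphere in the truncus pulmonalis for the
pulmonary valve, a 1 cm outer shell below the aortic valve for the
myocardium, its anterior-left and anterior-right quadrants for the coronary
territories, and a 2 cm inner margin for the deep structures (septum, AV
node, mitral valve).

How trustworthy are doses computed from such contours when several observers
delineate the same patients? `cardatlas` implements the full measurement
chain — surrogate construction, pairwise spatial agreement, DVH dose metrics,
and structure-specific variability statistics — together with a synthetic
multi-observer cohort generator, so the whole analysis can be exercised and
validated without clinical data.

## Geometry

Contours are closed triangle meshes in mm (patient frame: +x left,
+y anterior, +z cranial). All set operations go through voxelization: a voxel
belongs to a structure iff its **centre** lies inside the closed surface
(parity of ray crossings along z). This is deterministic, robust for
arbitrary observer meshes, and matches how treatment-planning systems
rasterize structures; the price is a discretization bias of order
(spacing / feature size), which is why the analysis grid default is 1 mm
isotropic — volume errors are then well below the ~5% CV scale of interest,
and the unit tests verify < 1% volume error at 1 mm with strictly decreasing
error at 2 → 1 → 0.5 mm for convex primitives.

Margin operations (`inner_margin()`, `outer_shell()`) use an exact Euclidean
distance transform of the voxel mask, so "2 cm symmetric inner margin" means
true Euclidean distance, not an iterated structuring element. One distance
transform per heart serves both the 1 cm shell and the 2 cm deep margin.

Mask-derived structures are turned back into surfaces, when needed, as the
voxel boundary (cuberille) surface: watertight by construction and enclosing
exactly the mask volume. A marching-cubes style smoother surface was
deliberately not implemented; the staircase bias (about half a voxel) is far
below the interobserver differences being measured.

### Numerical edge cases

* Ray-parity voxelization offsets every ray by a fixed sub-micrometre amount
  so rays cannot graze lattice-aligned edges of voxel-boundary meshes;
  degenerate columns are retried at three alternative offsets.
* A globally inverted mesh (negative signed volume) is repaired by flipping
  all faces with a warning; locally inconsistent orientation is an error that
  lists the offending edges.
* Margins larger than the structure's inradius produce an empty mask plus a
  warning, not an error — small synthetic hearts can legitimately lose their
  deep structures.

## Spatial agreement

For every structure and each of the `choose(k, 2)` observer pairs
(15 pairs for 6 observers) the package computes Dice and Jaccard overlap from
the voxel-boolean volumes, the Euclidean distance between solid centres of
mass (DCOM), and vertex-by-vertex surface distances: the symmetrized mean
(ASD) and the maximum (HD). Summaries are plain unweighted means over pairs
and patients; empty structures yield missing records that are excluded and
counted, never imputed.

Vertex-to-vertex distances are tessellation dependent, so both vertex sets
are thinned to roughly one point per 2 mm cell before the nearest-neighbour
computation (deterministic spatial binning, which for voxel-boundary surfaces
is equivalent to resampling to a ~2 mm mesh). A vertex-to-surface variant
(`method = "surface"`) and the two directed means (`verbose = TRUE`) are
available because the symmetrization convention is a genuine choice; the
defaults follow the common vertex-based definition.

## Dosimetry

Dose grids are regular scalar fields in Gy. The cumulative DVH is tabulated
at every 0.10 Gy bin edge (volume at-or-above dose, voxel centres, no
sub-voxel interpolation). The three reported metrics are:

* `DMEAN` — arithmetic mean over masked voxels (equal-volume voxels make it
  volume-weighted);
* `D2CC` — dose to the maximally exposed 2 cm³, obtained by linear
  interpolation on the binned cumulative DVH (a bin-floor variant is behind
  `interpolate = FALSE`; the two differ by at most one 10 cGy bin).
  Structures below 2 cm³ return their minimum dose flagged `"volume<2cc"`
  rather than erroring — synthetic pulmonary valves can drop that small;
* `V5GY` — relative volume at or above 5 Gy, read at the exact 5.0 Gy edge.

Dose metrics for observer structures are computed by running the *same*
atlas construction directly on the patient's dose grid (2.5 mm), instead of
resampling the 1 mm analysis masks: grids are never silently resampled
anywhere in the package.

## Variability models

Let `y_{spo}` be a positive quantity (volume, DMEAN, D2CC) for structure
`s`, patient `p`, observer `o`.

**CV (log-normal model).** `log y = m_{sp} + e`, with a fixed effect for
every structure-patient cell and structure-specific error variance σ².
Profiling the cell means leaves the residual sum of squares as the
sufficient statistic; under the conjugate inverse-gamma prior
IG(a = b = 0.001) the posterior of σ² is IG(a + df/2, b + SS/2), and
CV = sqrt(exp(σ²) − 1) is reported as the posterior median with the
equal-tailed 95% credible interval. This closed-form conjugate treatment
gives honest credible intervals without an MCMC dependency; the acceptance
tests verify |bias| < 2 pp and 90–98% coverage at a true CV of 10% under the
16 × 6 design.

**SD of V5GY (beta model).** Proportions get a beta regression with
logit-linked cell means and a structure-specific precision φ, fitted by
maximum likelihood (analytic gradients, BFGS). Because one mean per cell is
profiled out, the ML within-cell dispersion is biased; the implied variance
is rescaled by n/(n − C) (a REML-style degrees-of-freedom correction) before
conversion, which removes the ~9% downward bias visible at the 16 × 6 design
and restores nominal bootstrap coverage. The reported
SD = sqrt(μ(1 − μ)/(1 + φ)) uses the structure-level mean μ (average of cell
means); its 95% interval is a seeded parametric bootstrap (B = 1000 by
default). Values exactly 0 or 1 are compressed by (y(n−1)+0.5)/n; a structure
whose values are *all* 0 (or all 1) — e.g. a valve that never reaches
5 Gy — is flagged `not_calculated`, mirroring how such cells must be handled
in practice.

**ICC(2,1).** Two-way random-effects, absolute-agreement, single-rater
intraclass correlation from the ANOVA mean squares, with the standard
F-based (McGraw & Wong) 95% confidence interval. The point estimate is
checked against a from-scratch sums-of-squares oracle; simulation tests
verify |bias| < 0.02 and nominal coverage at a true ICC of 0.8. Up to 10%
missing cells are tolerated through the sequential ANOVA; more is an error
(no imputation). Note the CV and SD intervals are Bayesian credible
intervals while the ICC interval is a frequentist confidence interval; a
fully Bayesian ICC was considered out of scope.

## The synthetic cohort

The generator emulates the validation study's design: 16 patients, 6
observers per patient, CT slice thicknesses 10 mm (3 patients), 7.5 mm (4),
5 mm (1), 3 mm (8), true heart volumes drawn uniformly from 550–850 cm³
(an ellipsoid with mild low-order shape perturbation, longest axis
cranio-caudal), and one pair of tangential fields at 50 Gy whose border
crosses the anterior-left heart.

Per observer, the model applies:

1. a smooth zero-mean radial displacement field (orthonormal spherical
   harmonics to degree 4 with i.i.d. Gaussian coefficients, normalized so the
   pointwise SD equals `observer_sd`);
2. a cranio-caudal extent shift ~ N(0, (slice/2)²) followed by snapping of
   both extents to slice planes — the dominant noise for thick-slice
   patients;
3. landmark jitter ~ N(0, `landmark_sd`²) per axis, with 70% of the variance
   shared between the aortic-root and truncus landmarks (both are read off
   the same image region, so their errors correlate; fully independent
   errors would collapse the truncus-to-valve distance unrealistically
   often);
4. a log-normal jitter (SD 0.10) of the aortic-valve cone radius — the
   valve's extent is judged from poorly visible anatomy, so observers
   disagree about its size, not just its position;
5. atlas construction of all six substructures from the perturbed contour
   and landmarks.

Defaults were chosen once from the magnitudes the validation study reports:
`observer_sd = 2.5` mm (heart-surface deviations "typically below 3 mm"),
`landmark_sd = 6` mm (valve and myocardium cranial-end deviations up to
15 mm ≈ 2.5 σ), cone base radius 12 mm (a typical aortic-root radius; only
defined pictorially in the protocol), pulmonary "almost touches" gap 2 mm,
cone apex caudal. The anterior/left/right wall split uses two orthogonal
planes through the heart centroid (the wall boundaries are defined only
pictorially; planes are the simplest reproducible proxy, and the split
azimuth is a parameter for sensitivity analyses). "Below the aortic valve"
is implemented as z below the aortic-root plane.

The dose surrogate is
`dose(x) = base + (Rx − base)·σ(s/w) + scatter·(1 − σ(s/w))·exp(−max(−s,0)/λ)`
with s the signed distance to the field-edge plane, w = 4 mm penumbra,
base = 0.3 Gy out-of-field floor, scatter = 2 Gy with λ = 25 mm decay. The
plane offset is placed per patient by bisection so the true heart's V5GY hits
a target drawn uniformly from 4–22% per patient (mean 13%; plans genuinely
differ in how close the tangential border runs to the heart, and without
that spread the between-patient dose variation — and hence the dose-metric
ICCs — would be artificially small). Deep in the field the dose plateaus at
the 50 Gy prescription, far outside it tends to the base level.

Everything is driven by counter-derived substreams of one master seed
((patient, observer, purpose) → seed), so cohorts are byte-identical across
reruns and partial regeneration is reproducible. Perturbations that produce
degenerate geometry (collapsed contour, truncus swallowed by the aortic
valve) are resampled from the next substream, up to five times, with a
message.

### What the generator does and does not emulate

It reproduces the *statistical structure* the analysis assumes — smooth
interobserver contour noise, slice-quantization effects that scale with
slice thickness, landmark-driven valve variability, a steep tangential dose
gradient — and hence supports closed-loop validation: a target heart-volume
CV dialled into the generator is recovered by the estimation chain within
1.5 percentage points. It does **not** provide anatomically realistic
cardiac shapes, CT appearance, per-observer systematic bias (no gold
standard exists, so the observer effect is zero-mean by design; a bias term
would be a one-line extension), or clinical dose calculation. Passing tests
therefore demonstrate the correctness and calibration of the *measurement
chain*, not the clinical magnitudes of any particular cohort.

One consequence of modelling the slice quantization faithfully: under the
default slice mix the heart-volume CV cannot fall below about 5% no matter
how small the radial noise is — thick slices alone produce that much volume
uncertainty. `tune_observer_sd()` therefore resolves targets below the floor
to the floor when it is within 1.5 pp, and errors otherwise. (That floor
landing at the same ~5% the validation study reports for real observers is
a reassuring coincidence, not a calibration.)

Because the substructures are *derived* from the heart contour and
landmarks, their volume noise is inherited geometry: the shell-based
myocardium would vary *less* than the heart if only the radial field acted.
The observed ordering — heart lowest CV, then myocardium/walls, then deep
structures, valves worst — emerges from the root-plane crop (landmark
jitter) and the margin geometry, not from per-structure tuning.

## Problem sizes and runtime choices

The default analysis grid is 1 mm isotropic; dose grids are 2.5 mm. The full
default cohort (16 patients × 6 observers × 7 structures: 240 pairwise
records per structure, 672 structure masks per grid resolution) runs in a
few minutes on one CPU. Unit tests use smaller designs (2–3 patients,
2–3 observers, 2–3 mm grids) chosen so every property remains informative;
simulation tests for the estimators use 100–200 replicates with fixed seeds,
and the beta bootstrap uses B = 200 in tests versus B = 1000 as the
analysis default.

## Known limitations

* Vertex-based ASD/HD depend on the 2 mm thinning pitch; the surface-distance
  variant is provided but is not the default reported metric.
* The cuberille surfaces used for mask-derived structures carry a half-voxel
  staircase bias into ASD/HD for those structures (identical for both members
  of a pair, so pairwise differences are unbiased to first order).
* The beta model's structure-level mean is the unweighted average of cell
  means; with strongly unbalanced exposure across patients a weighted
  definition could differ.
* ICC intervals are frequentist while CV/SD intervals are Bayesian; the
  table labels each interval kind.
* The generator's valves inherit their variability from landmark and scale
  jitter only; real contouring may correlate valve errors with heart-surface
  errors in ways the model does not represent.
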