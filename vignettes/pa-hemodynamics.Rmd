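---
title: "Pulmonary artery wall shear and remodeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulmonary artery wall shear and remodeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahemo)
```

`pahemo` is a desk-scale pipeline for studying how pulmonary artery (PA)
geometry and wall shear relate to right-ventricular (RV) remodeling and
pulmonic valve replacement (PVR) in repaired tetralogy of Fallot (rToF).
This vignette is the package's own account of the science: the models,
their assumptions, every tunable that matters, and what the synthetic
generators do and do not emulate.

## The physical model

### Locally cylindrical wall shear

Real patient studies obtain wall shear stress (WSS) from a 3D
finite-element Navier–Stokes solve on a segmented PA. `pahemo` replaces
that solver with an analytic surrogate built on two classical solutions of
pipe flow, applied per wall point with the *local* radius and branch flow:

* **Steady**: Poiseuille flow. The wall value of $\mu\,du/dy$ for a
  parabolic profile carrying flow $Q$ through radius $R$ is
  $$\mathrm{WSS} = \frac{4\mu Q}{\pi R^3}.$$
* **Pulsatile**: Womersley flow. The inlet waveform is decomposed into 10
  Fourier harmonics; harmonic $k$ at angular frequency $k\omega$ drives an
  oscillatory pipe solution with Womersley number
  $\alpha_k = R\sqrt{k\omega\rho/\mu}$. Writing
  $\Lambda_k = i^{3/2}\alpha_k$ and $F(\Lambda) = 2J_1(\Lambda)/(\Lambda
  J_0(\Lambda))$, the complex wall-shear amplitude per unit complex flow
  amplitude is
  $$g(\Lambda) = \frac{-\mu\,\Lambda\,J_1(\Lambda)/J_0(\Lambda)}
  {\pi R^3\,(1 - F(\Lambda))},$$
  which reduces to the Poiseuille gain $4\mu/(\pi R^3)$ as
  $\alpha \to 0$. The shear time series is the real superposition over
  harmonics, directed along the local centerline tangent with the sign of
  the instantaneous flow.

The surrogate is linear and axisymmetric: it has no secondary flows, no
junction vortices, and no curvature-induced skewing. What it buys is exact
verifiability — every number it produces can be checked against a closed
form, which the test suite does. Externally computed CFD fields (e.g.
per-timepoint VTP exports) can be imported through
`load_external_wss_series()` and post-processed identically; the import
path accepts whatever per-point shear vector array the solver wrote and
does not re-derive it.

Assumptions inherited from the reference protocol: rigid walls, no-slip,
Newtonian blood with density 1.06 g/cm³ and viscosity 0.04 g/(cm·s) (CGS
units are used throughout the internals; mL and beats/min are converted at
the interface). The periodic steady state is emitted directly at 20 evenly
spaced timepoints per cycle rather than time-stepping transient cycles; the
conventional 2.5 s / 0.0001 s steady protocol (25,000 steps) is retained as
metadata in `run_config()` for provenance parity.

### Bessel evaluation

$J_0$ and $J_1$ of the complex argument $\Lambda = i^{3/2}\alpha$ are
computed by power series up to $|\Lambda| = 60$ (relative accuracy limited
only by term cancellation, ~1e-9 absolute near the switch) and by the
Hankel large-argument asymptotics of the *ratio* $J_1/J_0 \approx i -
1/(2\Lambda)$ beyond, so no overflow occurs at any physiological or
unphysiological $\alpha$.

## Derived metrics

With $\mathbf{w}(x,t)$ the shear vector at wall point $x$:

* time-averaged WSS: $\mathrm{taWSS}(x) = \frac1T\int_0^T
  |\mathbf{w}(x,t)|\,dt$. We use the field-standard
  magnitude-average convention; the alternative (magnitude of the vector
  average) carries no extra information here because it is exactly the
  numerator of the OSI.
* oscillatory shear index:
  $$\mathrm{OSI}(x) = \frac12\left(1 -
  \frac{\left|\int_0^T \mathbf{w}\,dt\right|}
  {\int_0^T |\mathbf{w}|\,dt}\right) \in [0, 0.5],$$
  0 for shear that never changes direction, 0.5 for zero-mean reversal.
  Points with identically zero shear get OSI 0 by convention (warned).
* systolic/diastolic WSS: $|\mathbf{w}|$ at the output timepoints where the
  *inlet* flow is maximal/minimal (ties to the earliest index). Locating
  them on the 20 saved timepoints, not the continuous waveform, mirrors how
  saved CFD outputs are actually interrogated.

Quadrature over the cycle is periodic trapezoidal on the uniform output
grid (which equals the plain sample mean with the wrap-around sample
implied). Segment summaries are area-weighted averages (one third of
incident triangle area per vertex, hence mesh-resolution invariant) and
maxima; a quantile "peak" (e.g. 0.99) is exposed to probe sensitivity to
single-point outliers. Flow extensions are trimmed *before* segment
division, and the whole-vessel row is the union of MPA, LPA and RPA.

## Centerline geometry

Curvature is $\kappa = |c'\times c''|/|c'|^3$ with derivatives from cubic
smoothing splines fitted per coordinate against arclength after resampling
at 0.1 cm. The smoothing penalty defaults to `lambda = 1e-8`
(near-interpolating), appropriate for clean synthetic or pre-smoothed
centerlines; raise it for noisy extracted ones. Two numerical facts shape
the defaults and the tests:

* natural spline boundary conditions force $c'' \to 0$ at the path ends, so
  $\kappa$ is biased low within roughly five resampled points of each end.
  The reported `mean_kappa` therefore excludes the endpoints (and accuracy
  claims in the tests exclude a ten-point end margin); on a radius-2 circle
  at 0.1 cm the endpoint-excluded mean is within 0.7% of 1/r.
* the input polyline must sample the true curve finely relative to the
  0.1 cm resampling step: linear-interpolation sag of a coarse input
  ($h^2\kappa/8$) is amplified by the second derivative into a visible
  curvature ripple.

Tortuosity is $\mathcal{X} = L/D - 1$; closed loops ($D < 10^{-9}$ cm) are
an error rather than an infinity. Branch metrics are computed on full
inlet-to-outlet paths (trunk joined to branch), matching how left/right PA
paths are conventionally reported. Because resampling is uniform, the
point-mean and arclength-weighted mean of $\kappa$ coincide, so the choice
between them is moot by construction.

Branch splitting assigns each wall point to the nearest branch centerline
(ties deterministically MPA < LPA < RPA). Full paths sharing the trunk
prefix are truncated where the left and right paths diverge beyond 1.0
local MPA radius — a radius-scaled threshold is size-invariant. Flow
extensions extrude each open boundary loop along its outward best-fit
normal for 5 local diameters (non-planar loops beyond tolerance warn and
use the best-fit plane).

## Boundary conditions

Steady inflow is stroke volume × heart rate. The stroke volume convention
is **net** forward volume (forward − regurgitant) by default, because that
is what an indexed RV stroke volume measures; `sv_convention = "forward"`
switches to forward-only. Outlets are resistances in indexed Wood units
(iWU); parallel combination and conductance-proportional flow split give
the branch flows (2 iWU at each branch outlet → 1 iWU total for the
lungs, an even split for equal branches). The indexing convention is
iWU = WU × BSA (so absolute resistance = iWU/BSA, converted at 1 WU =
1333.22/16.6667 ≈ 80 dyn·s/cm⁵); this is the conventional direction for
BSA-indexed pediatric pulmonary resistance and is recorded in the output
manifest. RCR/Windkessel outlets are out of scope: they need distal
pressure or flow data that the modeled setting does not provide.

The "10 Fourier nodes" of the inlet mapping are implemented as 10
harmonics (mode 0 plus 9 oscillatory modes); the count is exposed as
`n_fourier_modes` should a different reading be wanted.

## Synthetic generators: what they emulate

### Geometry

`default_pa_spec()` builds a bowed 4-cm MPA trunk (radius 1.2 cm) and two
circular-arc branches leaving the junction at a 0.7 rad opening half-angle:
LPA radius 0.8 cm on a 2.2 cm arc, RPA radius 0.9 cm on a 2.6 cm arc
(sweeps 1.4/1.2 rad). These defaults encode the two robust anatomical
orderings of the disease — the left PA is narrower *and* curvier than the
right — so the pipeline reproduces LPA > RPA > MPA in average steady WSS
and LPA > RPA in path curvature. Branch walls start 0.75 MPA radii past
the junction because a segmented anatomy has no branch wall inside the
trunk; the ground-truth centerlines still originate exactly at the
junction. Not emulated: non-circular lumens, stenotic webs, surface noise,
and real ostial geometry — so a 95% label-recovery figure on this geometry
says nothing about segmenting a noisy patient surface.

### Flow

`waveform_spec()` produces two raised-cosine lobes: a systolic forward
lobe (default 40% of the cycle) integrating to the forward volume and a
diastolic reverse lobe integrating to RF × forward volume. Defaults:
75 bpm; RF 0.40 (the cohort-typical median for significant pulmonary
regurgitation); forward volume 153.3 mL chosen so the net output is
~92 mL/beat, i.e. an indexed RV stroke volume of ~71 mL/m² at a BSA of
1.3 m² (a typical 12-year-old). The shape is smooth and band-limited
enough that 10 harmonics reconstruct it to a fraction of a percent; real
PC-MRI waveforms (dicrotic notches, measurement noise) can be supplied as
tables. One deliberate consequence: an axisymmetric engine plus RF 0.4
reverses shear *everywhere*, so synthetic OSI values (~0.45) sit well above
the ~0.2 typical of real vessels, where secondary flows break the
uniformity. Qualitative orderings (MPA OSI highest) survive; absolute OSI
levels are not to be compared with patient values.

### Cohort

`make_synthetic_cohort()` draws sex (41% male), age at first scan
(lognormal, median 12 y), inter-scan gap (~3.5 y), RF (Beta, mean 0.40),
and hemodynamic predictors (lognormal around a whole-vessel steady WSS of
6.16 dynes/cm²) — scales matched to a typical rToF CMR cohort. RVEDVi is
the generative outcome: baseline 145 mL/m² plus the requested
predictor effects (applied to centered predictors), covariate effects, and
Gaussian noise (SD 20 mL/m²); RVEF is drawn independently and RVSVi/RVESVi
follow from the volumetric identities. Event times are exponential with the
log-hazard linear in centered predictors; censoring replaces a fraction
(default 0.7, matching ~6/22 events) with a uniform time before the event.
All randomness flows from one integer seed; the RNG identity is stored in
the output attributes. This generator validates *estimator recovery*
(unbiased OLS/Cox under the true model), not robustness to the
misspecification, measurement error, or informative censoring of real
registries.

## Statistics stage

Each predictor gets its own linear model, adjusted a priori for sex and the
ages at both scans; the effect estimate is the predictor coefficient in
outcome units per predictor unit. Benjamini–Hochberg adjustment is applied
within each outcome's table (the per-table family, matching how such
results are reported); a global family is a one-line change via
`bh_adjust()` on the pooled p-values. Patients with PVR between scans are
excluded from remodeling fits — in `run_cohort_study()` the synthetic
cohort has no such patients, and the audit log records all exclusions.

Cox models adjust for age at first scan and sex; hazard ratios are per unit
or, with `normalize = TRUE`, per SD (the two coefficients are related
exactly by the predictor SD, which the tests assert). The Schoenfeld
correlation-with-time check is reported at α = 0.05 but never drops a
variable. Monotone likelihoods (perfect separation) are flagged via the
fitter's warnings plus a coefficient/SE magnitude guard, not silently
returned as converged.

For ROC cutoffs we dichotomize at the median event time: event at or
before the median → 1, followed to or past the median event-free → 0,
censored before the median → excluded (their landmark status is unknown;
labeling them 0 would misclassify unknown outcomes). The cutoff maximizes
sensitivity + specificity over all midpoints between adjacent sorted unique
scores, in both directions, with ties resolved to the smallest qualifying
cutoff; the tests pin it to an exhaustive brute-force oracle and to an
independent ROC implementation. Kaplan–Meier curves use the standard
product-limit estimator.

## Numerical choices and degenerate inputs

* Periodic trapezoid everywhere a cycle is integrated; uniform sampling is
  enforced, not assumed.
* OSI is clamped to [0, 0.5] against round-off; collinear centerline
  stretches report κ = 0, never NaN.
* Equidistant wall points, equal ROC criteria, and equal flow extrema all
  break ties deterministically (lowest enum order / smallest cutoff /
  earliest index), so reruns and point reorderings are reproducible.
* Degenerate requests error early with the offending quantity named:
  RF ≥ 1, non-positive resistances, closed-loop tortuosity, zero-event Cox
  fits, one-class ROC, empty analysis region after trimming.

## Problem sizes

The default meshes (40 axial × 20 circumferential rings per tube, ~2,400
wall points) resolve segment-averaged WSS to well under 1% — refining to
45 × 24 moves averages by < 0.02% — and one full case runs in a fraction
of a second, so the test suite and cohort studies use 24–30 ring meshes
and 8–12 patient cohorts. Statistical recovery tests use n = 500 patients
and 100-replicate coverage loops, sized to keep the whole suite around ten
seconds.

## Known limitations

* No junction fluid mechanics: branch flows come from the resistance
  network alone, and shear directions are purely axial.
* Absolute pulsatile metrics (taWSS, OSI, systolic WSS) are
  surrogate-specific; only steady WSS magnitudes and all qualitative
  orderings should be compared across engines. For real CFD output, use the
  import path.
* The cohort generator has no between-scan PVR subjects, no missing data,
  and no competing risks.
* Centerlines must be supplied or generated; medial-axis extraction from
  arbitrary meshes is out of scope.
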