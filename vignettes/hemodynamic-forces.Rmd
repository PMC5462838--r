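---
title: "Quantifying left-ventricular hemodynamic forces from 4D flow velocity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular hemodynamic forces from 4D flow velocity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoforce)
```

## The physical model

Time-resolved three-directional phase-contrast MRI ("4D flow") measures the
blood velocity vector $v(x, t)$ in every voxel of a volume covering the
heart, over one reconstructed cardiac cycle. Inside the left-ventricular
(LV) blood pool the momentum balance of an incompressible Newtonian fluid
relates the velocity field to the pressure gradient:

$$\nabla p \;=\; -\rho\,\frac{\partial v}{\partial t}
  \;-\; \rho\,(v \cdot \nabla)\,v \;+\; \mu\,\nabla^2 v,$$

with blood density $\rho = 1060\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 0.004\ \mathrm{N\,s/m^2}$ (package defaults, `fluidConstants()`);
gravity and other body forces are omitted because they are spatially
uniform over the cavity and do not alter intraventricular gradients.
Integrating $\nabla p$ over the segmented LV lumen $\Omega(t)$ gives the
net force the blood exerts on the myocardial walls at each time frame,

$$F(t) \;=\; \int_{\Omega(t)} \nabla p \; dV,$$

the *hemodynamic force*. In a synchronously relaxing ventricle the
diastolic filling force is expected to align with the main inflow
direction (base to apex). Conduction abnormalities such as left bundle
branch block desynchronize relaxation, and the filling force acquires a
larger component orthogonal to the long axis. The package quantifies this
with two scalar metrics per phase window $W$:

* `ratioMax`: $\max_{t \in W} |F(t)\cdot \hat{s}| \,/\, \max_{t \in W}
  |F(t)\cdot \hat{l}|$, where $\hat{l}$ is the apex-to-base long-axis unit
  vector and $\hat{s}$ the anteroseptal-to-inferolateral short-axis unit
  vector. The two maxima are searched independently; they need not occur
  at the same frame.
* `ratioRms`: $\mathrm{rms}_{t \in W}(F\cdot\hat{s}) \,/\,
  \mathrm{rms}_{t \in W}(F\cdot\hat{l})$, a temporally global companion
  less sensitive to single-frame noise.

Both are evaluated over full diastole and over the early (E-wave) and late
(A-wave) filling windows separately.

### The RMS definition

Two inequivalent readings of the RMS metric circulate: the ratio of the
two RMS force components, and the RMS of the per-frame force-ratio time
series. They differ whenever the components' time profiles differ in
shape. This package implements the ratio-of-RMS form as the default
(`ratioRms(..., definition = "ratio_of_rms")`) because it stays bounded
when the long-axis component crosses zero at isolated frames; the
RMS-of-ratio alternative is available behind
`definition = "rms_of_ratio"` and is excluded from defaults and reports.

### Axis construction

Clinically the long and short axes are read off standard imaging views.
For a fully algorithmic definition the package derives them from three
anatomical landmarks: $\hat{l}$ points from the apex to the mitral annulus
centre, and $\hat{s}$ is the component of (mitral $-$ aortic) orthogonal
to $\hat{l}$, i.e. the in-plane direction of the three-chamber view from
the anteroseptal towards the inferolateral side. Orthonormality holds by
construction and the frame is exactly equivariant under rigid rotations of
the landmarks.

## Numerical scheme

**Masked spatial derivatives.** The per-frame binary lumen mask is the
boundary condition: derivatives use central differences where both axis
neighbours are inside the mask, one-sided differences where only one is,
and are flagged missing (contributing zero to the integral) where neither
is. Outside-mask voxels never supply values, so myocardial and
extracardiac velocities cannot leak into the cavity derivatives. The
Laplacian is assembled as the divergence of the masked gradient, which
keeps the same boundary-condition discipline and is exact for quadratic
fields on interior voxels (wide five-point second-difference stencil).

**Temporal derivative.** The reconstructed cycle is periodic, so
$\partial v/\partial t$ uses cyclic central differences over the cardiac
cycle, computed on the full velocity field *before* masking: velocity data
exist beyond the moving lumen boundary, and differentiating before masking
avoids spurious spikes where the mask moves between frames.

**Convective term.** Evaluated in advective form $(v\cdot\nabla)v$,
matching the momentum-balance expression term by term.

**Accuracy.** Both stencils are second order. On the analytic phantoms at
2.8 mm / 40-frame sampling (the acquisition the generator emulates) the
worst interior-voxel error against the closed forms is about 0.4% of the
peak gradient for the oscillating uniform field (pure inertia), and at
machine precision for the steady stagnation (pure convection) and
Poiseuille (pure viscosity) fields, whose velocity profiles are polynomial
and therefore differentiated exactly. Halving the frame interval shrinks
the inertial error fourfold, the expected $O(\Delta t^2)$ behaviour; this
is verified by the test suite and recomputed by `scripts/acceptance.R`.

**Missing-gradient convention.** In-mask voxels whose neighbourhood is too
thin to difference along some axis (e.g. a one-voxel protrusion)
contribute zero to that axis of the force integral: only defined
information is integrated, and the affected voxel fraction vanishes as the
cavity grows.

## Preprocessing

* **Background phase offsets** (eddy-current-like, time-invariant): a 3D
  polynomial of total degree 4 per velocity component is least-squares
  fitted in scaled world coordinates to the *temporal-mean* velocity over
  static-tissue voxels and subtracted from every frame. Fitting the
  temporal mean rather than per-frame surfaces encodes the static nature
  of the artifact and makes the correction idempotent. The fit refuses
  rank-deficient designs (e.g. co-planar static voxels).
* **Static-tissue detection**: a voxel is static when both the temporal
  standard deviation and the temporal mean of its speed are below one
  threshold (default 0.02 m/s). A single interpretable threshold keeps
  the rule honest and testable; when the background offset itself exceeds
  the threshold the caller must supply a static mask (`runSubject(static=)`),
  since speed-based detection cannot see through an offset larger than
  its own gate.
* **Temporal phase unwrapping**: velocities alias into $(-v_{enc},
  v_{enc}]$ by multiples of $2 v_{enc}$. Scanning frames in order, each
  consecutive-frame jump larger than $v_{enc}$ is reduced by the multiple
  of $2 v_{enc}$ that minimizes it. The first frame is taken at face
  value, so wraps already present there are unresolvable — the intrinsic
  limit of any purely temporal algorithm. Applied per component; no
  spatial or multi-venc unwrapping is attempted.
* **Mask re-timing**: a segmentation drawn on a different frame count is
  resampled by nearest-neighbour assignment in cycle-normalized time —
  binary-safe, no invented morphology.
* **Quality control**: through-plane flow is integrated over user-defined
  discs at the mitral (diastole) and aortic (systole) orifices using a
  deterministic 32×8 polar quadrature with trilinear velocity sampling;
  subjects whose inflow/outflow volumes disagree by more than 15% fail the
  gate, mirroring the exclusion criterion used when curating such cohorts.

## Phase detection

Two speed probes (trilinear interpolation of the velocity magnitude) near
the mitral and aortic orifices drive a fully algorithmic segmentation —
replacing the human-in-the-loop streamline inspection used clinically,
since reproducibility requires removing the manual step:

1. Systole is the contiguous run of frames around the global aortic-speed
   peak where the speed stays above `onsetFraction` (default 0.25) of the
   peak; diastole is the rest of the cycle.
2. The mitral curve is smoothed with a 3-frame moving average (at ~50 ms
   sampling a single-frame noise peak is plausible); candidate filling
   peaks are its diastolic local maxima above `onsetFraction` of the
   diastolic maximum (the prominence floor that makes detection
   noise-robust). The first candidate is the E peak, the last the A peak,
   and the E/A boundary the global minimum strictly between them.
   Interval end points use the raw series.
3. If fewer than two separable peaks exist — e.g. E and A fused by a short
   diastasis — the E/A split is flagged undefined; the subject keeps its
   full-diastole metrics and is dropped from E/A-specific statistics only.

## Cohort statistics

Group comparisons are gated on normality: the Lilliefors test
(Kolmogorov–Smirnov against a normal with estimated moments) is run per
group, and both-normal metrics go to a pooled-variance two-sample t-test
(df $= n_1+n_2-2$), anything else to the Wilcoxon rank-sum test. All tests
are two-sided at $\alpha = 0.05$ with no multiplicity correction,
following the reporting convention of small physiological cohorts. Choices
worth stating:

* The pooled (not Welch) t-test is the default: applied to the published
  septal–lateral delay summaries (57.6 ± 62.0 ms, n = 9 vs −4.4 ± 54.9 ms,
  n = 9) it reproduces the printed p-value 0.039, which is the only
  internal evidence of the variant used.
* Lilliefors p-values come from a seeded Monte-Carlo null ($10^4$
  standard-normal samples of the same size) rather than lookup tables:
  no interpolation ambiguity, assertable to the digit, and cached per
  sample size so cohort simulations pay one statistic evaluation per call.
* The Wilcoxon test enumerates all rank assignments when $n_1+n_2 \le 12$
  (exact, ties handled via midranks) and uses the tie-corrected normal
  approximation otherwise.
* `ttestFromSummary()` applies the same formulas to sufficient statistics,
  for re-analysis of published mean ± SD tables.

Linear regression of the E- and A-wave ratios on QRS duration and on the
septal–lateral mechanical delay uses ordinary least squares with the
slope's t-test.

## The synthetic-data generator

No public patient data exist for this pipeline, so every stage is
exercised on synthetic inputs whose ground truth is known by construction.

**Analytic phantoms** (`genAnalytic`) carry closed-form pressure
gradients: an oscillating spatially uniform field (inertia only), planar
stagnation flow (convection only), and steady Poiseuille pipe flow
(viscosity only). Together they cover every term of the momentum balance
and provide the central cross-module contract: the estimator must match
the `gradp` callable within the stated tolerances.

**The LV filling phantom** (`genLVPhantom`) emulates the study object: a
half-ellipsoidal lumen (about 95 ml end-diastolic, truncated at the base
plane) whose short semi-axes shrink ~35% in volume during systole and
re-expand in diastole, with three Gaussian-profile jets under half-sine
envelopes — systolic outflow toward the aortic orifice (frames 1–15 of
40), E-wave inflow (frames 19–28) and A-wave inflow at 60% amplitude
(frames 32–39), at the default 1 m/s peak speed, 10 mm jet radius,
2.8 mm isotropic 32×32×48 grid and 40 frames over 1 s. The controllable
pathology surrogate is the E-jet angle: the inflow jet is tilted from the
apex-directed long axis within the three-chamber plane, toward the
inferolateral wall. Because the early-filling force is dominated by the
inertial term along the jet axis, `ratioMaxE` rises essentially as
$\tan(\theta)$ — the dose-response the acceptance checks verify over
$\theta \in \{0°, 15°, 30°, 45°, 60°\}$.

The phantom velocities are kinematic constructions, not solutions of the
Navier–Stokes equations; that is adequate because the pipeline estimates
$\nabla p$ from whatever velocity field it is given and the analytic kinds
carry the exact physics. What passing phantom tests therefore shows is
that the *estimator and metrics* are correct, not that real LBBB ventricles
behave like tilted jets: real data add measurement noise, segmentation
error, partial-volume effects at the moving wall and respiratory
artifacts, none of which the phantom reproduces (noise injection is
available via `noiseSigma`, aliasing and polynomial offsets via
`injectArtifacts`).

**Cohort simulation** (`genCohort`) draws per-subject E-jet angles from
two group distributions (defaults 45° ± 8° vs 10° ± 8°, n = 9 + 9,
matching the study's group sizes) and couples a QRS duration to the angle
through a linear model (90 ms + 1.5 ms/deg + 12 ms noise), emulating the
empirical conduction-delay/jet-discordance association without claiming a
mechanism.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use: the full 32×32×48 / 40-frame
grid for the analytic-oracle and jet-angle checks; a geometrically
identical 16×16×24 / 24-frame phantom for cohort-scale orchestration
tests; 2000 null replicates (n = 9 + 9) for the type-I calibration of the
gated comparison and 500 replicates per arm for the power ordering of the
published E-wave (1.05 ± 0.41 vs 0.63 ± 0.19) versus A-wave (0.37 ± 0.2 vs
0.26 ± 0.11) ratio summaries; and 50 seeded noise draws at SNR 10 for
phase detection. Every generator is a pure function of its spec including
the seed; all simulation seeds are fixed in code or derived from the
acceptance script's `--seed`.

The large-replicate calibration examples for the full phantom-cohort
path (hundreds of seeds through the complete image pipeline) are run at
reduced subject counts in the tests; the statistical calibration itself is
established on the summary-level simulations above, where replication is
cheap and the estimand identical.

## Known limitations

* Absolute pressure is not recovered (no Pressure–Poisson solve); only
  gradients and their volume integral are used.
* The viscous term is resolution-limited in thin shear layers; for
  volume-integrated forces its contribution is minor.
* Registration between the segmentation series and the flow series is
  accepted as user input (a rigid offset); no automatic correction.
* Wraps present at the first frame, and background offsets larger than
  the static-speed gate, are outside what the respective corrections can
  recover; both limits are inherent to the chosen (and deliberately
  simple) algorithms.

## A minimal worked example

```{r example, eval = FALSE}
ph <- genLVPhantom(phantomSpec(kind = "lv_filling", eJetAngle = 45))
row <- runSubject(ph$flow, ph$mask, ph$landmarks,
                  unwrap = FALSE, backgroundCorrect = FALSE)
row[, c("ratio_max_E", "ratio_max_A", "e_defined")]
```
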