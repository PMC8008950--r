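---
title: "Arterial wall mechanics from pressure-myograph recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial wall mechanics from pressure-myograph recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(arterymech)
library(dplyr)
```

# The measurement problem

A pressure myograph cannulates a small artery (mouse carotid scale, a few
hundred micrometres outer diameter), controls the lumen pressure and the
axial length, and records outer diameter and axial force. Two test types
characterise the passive biaxial behaviour:

* **Force-length tests**: the vessel is stretched axially in 10% increments
  of its unloaded length while held at a constant pressure, repeated at
  several pressures (90, 120 and 140 mmHg by default). A striking property
  of arteries is that these force-stretch curves (nearly) intersect at a
  single point: the axial stretch at which force is insensitive to pressure.
  That crossover is the **in-vivo stretch (IVS)** — an estimate of the
  stretch the vessel sustains in the animal, and a sensitive marker of axial
  remodelling (it falls with ageing and with stiffening disease).
* **Pressure sweeps**: held at its IVS, the vessel is pressurised in 10 mmHg
  steps from 0 to 140 mmHg while the outer diameter (and, as a quality
  control, the axial force) is recorded.

From these, the package derives loaded geometry, biaxial Cauchy wall
stresses, stress-stretch curves, and tangent moduli, and compares groups of
animals with the statistics conventional in this literature.

# Kinematics and stress

## Incompressibility

The arterial wall is treated as incompressible: the wall cross-sectional
area times the axial stretch is conserved,

$$\pi\left(r_o^2 - r_i^2\right)\lambda_z = \pi\left(R_o^2 - R_i^2\right),$$

where capital letters denote the unloaded (unstretched, unpressurised)
reference state. Since the instrument measures the loaded outer diameter
$2 r_o$, the loaded inner radius and wall thickness follow as

$$r_i = \sqrt{r_o^2 - (R_o^2 - R_i^2)/\lambda_z}, \qquad h = r_o - r_i.$$

The circumferential stretch uses the mid-wall radius by default,
$\lambda_\theta = (r_i + h/2)/(R_i + H/2)$; an inner-wall convention
($r_i/R_i$) is available via `stretch_ref = "inner"` because source
protocols differ on this point and the choice is rarely reported.

## Mean Cauchy wall stresses

Stresses are the mean (Laplace / free-body) forms standard in the
pressure-myography literature:

$$\sigma_\theta = \frac{P\, r_i}{h}, \qquad
  \sigma_z = \frac{f + P \pi r_i^2}{\pi h (2 r_i + h)},$$

with $P$ the lumen pressure (converted at 1 mmHg = 0.133322 kPa), $f$ the
transducer force (the pressure term adds back the thrust on the closed
cannula cap). Geometry is carried in micrometres and force in millinewtons,
which makes the stresses come out directly in kPa; both stress functions
normalise their inputs so the values are independent of the length unit.
The thin-wall hoop stress equals the wall-average of the thick-wall Lamé
solution exactly, which the test suite verifies by numerical integration.

## Curves and tangent modulus

The **circumferential stress-stretch curve** takes one point per pressure
step of the sweep performed at the sample's IVS; the **axial curve** takes
one point per stretch step of the force-length test at a context pressure
of 90 mmHg (80 mmHg is supported for protocols on very young animals, where
140 mmHg sweeps are not tolerated).

The **tangent modulus** $E_{tan} = d\sigma/d\lambda$ is estimated by a local
least-squares line over a sliding window of 5 points (one-sided at the curve
ends), with a central-difference alternative. Neither choice is canonical in
the literature, so both are exposed. Note the discretisation caveat: on the
10 mmHg / 10%-increment protocol grids the windowed slope of a strongly
convex curve can deviate from the true derivative by 15-30% where the grid
is coarse relative to the curvature; on dense noiseless grids (2 mmHg steps)
it is accurate to better than 1%. The validation suite therefore checks
exactness on linear curves at any density and 2% agreement with the analytic
derivative on dense simulated sweeps.

# IVS estimation and quality control

Real force-stretch curves only approximately share a point. The estimator:

1. interpolates each pair of curves piecewise-linearly (no spline — robust
   at the protocol's 10% grid density) and finds the zero of their
   difference; where several zeros exist it prefers the physically expected
   crossover (higher-pressure curve passing from below to above), falling
   back to the zero nearest the midpoint of the shared span;
2. averages all pairwise crossings (the arithmetic mean was chosen over a
   least-squares common point for transparency) and retains the maximum
   deviation of the crossings from the mean as a diagnostic `spread`;
3. flags — rather than drops — results supported by fewer than two usable
   crossings.

**Axial-force QC.** The IVS determination is validated through the pressure
sweep: if the vessel really is at its in-vivo stretch, the recorded axial
force should barely change with pressure. Samples whose force deviates from
its across-pressure mean by more than 25% (relative) are excluded; the
threshold is configurable, and pressure steps below 20 mmHg are excluded
from the statistic because near-zero forces make the relative deviation
numerically unstable (source protocols are silent on this point; the floor
is this package's documented choice).

# The synthetic artery

No raw myograph recordings are publicly deposited for this class of
experiment, so validation rests on a forward simulator with known ground
truth.

## Constitutive model

A thin-wall (membrane), incompressible four-fiber-family strain energy:

$$W = \frac{c_{iso}}{2}(I_1 - 3) + \sum_{k=1}^{4}
  \frac{c_1^k}{4 c_2^k}\left\{\exp\left[c_2^k (\lambda_k^2 - 1)^2\right] - 1\right\},$$

with $\lambda_k^2 = \lambda_\theta^2 \cos^2\alpha_k + \lambda_z^2
\sin^2\alpha_k$ and fiber families oriented circumferentially, axially and
along a symmetric diagonal pair at $\pm 45^\circ$ from the circumferential
axis. Mean Cauchy stresses follow in closed form
($\sigma_\theta = \lambda_\theta\, \partial W/\partial \lambda_\theta$ with
the radial stretch eliminated by incompressibility), and equilibrium
$P = \sigma_\theta h / r_i$ is solved for $\lambda_\theta$ by bracketed,
vectorised bisection on $g(\lambda_\theta) = \sigma_\theta h - P r_i$
(the multiplied-through form removes the $1/r_i$ singularity at the
degenerate lower bound). Every emitted point is verified to satisfy
equilibrium to better than $10^{-8}$ in relative pressure units. The
simulated transducer force subtracts the pressure-on-cap thrust, so the
recorded quantity matches what a myograph force transducer reports.

Residual stress (opening angle), smooth-muscle tone, viscoelasticity and
preconditioning hysteresis are deliberately out of scope: the simulator
emulates the *passive, preconditioned* state that the analysis pipeline
assumes. Real recordings additionally contain drift, hysteresis and
segmentation artefacts that additive Gaussian noise does not reproduce, so
passing tests demonstrate correctness of the analysis chain, not robustness
to every instrument pathology.

## Ground-truth IVS and calibration

The ground-truth IVS is defined **operationally** — the minimiser, over a
fine axial-stretch grid (step $10^{-4}$), of the across-pressure relative
spread of the noiseless equilibrium force — rather than as a model
parameter, because the model's curves, like real ones, only approximately
intersect. A coarse-to-fine scan accelerates the brute-force search; the
two stages agree because the spread profile is unimodal in the calibrated
regime.

Default parameter values were set once, as follows, and then frozen:

* Unloaded geometry 400 um outer diameter, 60 um wall: mouse-carotid scale,
  consistent with mounting on 380 um cannulas.
* $c_{iso} = 26$ kPa and fiber stiffnesses of a few kPa with exponents
  $c_2 \le 0.3$: chosen so that at 90-140 mmHg the model sits at
  circumferential stretches near 1.5-1.7 and hoop stresses of 100-250 kPa,
  with transducer forces in the single-digit mN range — the magnitudes
  typical of murine carotid myography. Softer exponents are also what keeps
  the force-spread criterion well-posed: with strongly exponential fibers
  the forces at large stretch converge in *relative* terms and the spread
  minimiser degenerates to the grid boundary.
* The diagonal-family stiffness is the calibration knob for the IVS
  setpoint. The axial family cannot serve: its stress contribution at fixed
  $\lambda_z$ does not depend on $\lambda_\theta$, hence not on pressure, so
  it shifts all force-length curves equally and leaves their crossover
  unchanged. Stiffer diagonal fibers lower the IVS — the same direction as
  the stiffening phenotype. `calibrate_ivs()` root-finds the multiplier.
* The `"control"` preset is calibrated to an IVS of 1.85 and the `"stiff"`
  preset — with twofold circumferential and diagonal stiffness, so its
  circumferential stress-stretch curve is left-shifted — to 1.79, matching
  reported cohort means for healthy young and prematurely stiffened vessels.
* Measurement noise: additive Gaussian, SD 2 um on outer diameter and
  0.05 mN on force (video dimension analysis and transducer scale noise);
  pressure and stretch are treated as exactly controlled.
* Biological variability: each animal's stiffness coefficients are jittered
  log-normally (SD 0.12 on the log scale, the diagonal pair sharing one
  factor to preserve symmetry) and the unloaded geometry with 4% CV. This
  yields cohort IVS standard deviations near 0.03-0.05, the range reported
  for real cohorts.

## What the recovery tests show

With 200 replicate cohorts at realistic group sizes (13 control / 9 stiff),
the pipeline recovers the group IVS setpoints to within two standard errors
at the cohort scale (per-sample SD / $\sqrt{n}$). Two small systematic terms
are worth knowing about, both far below what a real cohort could resolve:
piecewise-linear interpolation of convex force curves on the 10% protocol
grid biases the estimated crossing by about $-7\times10^{-4}$ stretch units
(the same discretisation acknowledged by the 0.005 oracle-agreement band),
and the log-normal parameter jitter shifts the *population mean* IVS off the
setpoint by about $+2\times10^{-3}$ because the IVS is a mildly nonlinear
function of the parameters.

# Cohort statistics

Group curves are summarised pointwise on the shared x-grid (pressure steps
for sweeps, stretch steps for force-length curves) as mean ± SE or SD;
points with $n < 2$ are flagged.

Curve comparisons follow the field convention of **pressure-matched
points**: the circumferential comparison uses the stretch reached at each
pressure step as the response (a left-shifted, stiffer vessel reaches less
stretch at matched pressure), the axial comparison uses the stress at each
stretch step. The model is a classic two-factor fixed-effects ANOVA with
interaction, fitted by least squares with sequential sums of squares
(identical to the cell-mean decomposition in the balanced case). Repeated
points from the same artery are treated as the second fixed factor, not as
a subject random effect; this matches the convention in the source
literature but understates within-artery correlation, so the group-effect
p-values should be read as descriptive of curve separation rather than as
strictly calibrated — the package's null simulations show correct type-I
error under independence, which is the model's assumption, not a property
of repeated-measures data.

Two-group location tests use the two-tailed **Mann-Whitney** test: exact by
full enumeration of rank arrangements when the combined sample size is at
most 16 and there are no ties ($p = \min\{1, 2\min[P(U \le u), P(U \ge u)]\}$),
otherwise a normal approximation with mid-rank tie correction and continuity
correction. Families of post-tests are adjusted by the step-down
**Holm-Šidák** procedure, $1 - (1 - p_{(i)})^{m - i + 1}$ with a running
maximum. Significance is starred at 0.05 / 0.01 / 0.001.

# Numerical choices, degenerate inputs, problem sizes

* Equilibrium bisection: 90 iterations on a bracket found by expansion;
  failure to bracket names the offending $(P, \lambda_z)$.
* `loaded_geometry()` rejects outer diameters below the incompressibility
  bound $2\sqrt{(R_o^2-R_i^2)/\lambda_z}$ by sample and row.
* Curves are sorted by stretch before differentiation, making tangent
  moduli invariant to row order; windows wider than the curve are shrunk
  with a warning, never silently.
* QC with non-positive mean force returns `NA` and flags the sample.
* Per-sample pipeline failures quarantine the sample with a recorded
  reason; the run aborts only if a whole group drops out.
* Validation problem sizes (chosen to exercise the statistics at
  cohort-realistic scale): 200 replicate cohorts for IVS recovery, 500
  replicates for the ANOVA null, 1000 replicates for the noise-expectation
  check, enumeration oracles up to $8+8$.

# Known limitations

* The membrane (thin-wall) stress model ignores transmural stress
  gradients; the thick-wall comparison bounds the discrepancy at
  $O(h/r_i)$.
* The simulator's noise model is additive and homoscedastic; it does not
  emulate drift, hysteresis, or preconditioning history.
* The two-way ANOVA ignores within-artery correlation (see above); a
  mixed-effects alternative is out of scope by design.
* Constitutive-parameter fitting to experimental curves is a non-goal: the
  four-fiber model here is a data generator, not an inference target.

# A complete run

```{r pipeline, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 11))
analysis <- run_pipeline(
  cohort$recordings, cohort$geometry, cohort$metadata,
  pipeline_config(reference_group = "control")
)
glance(analysis)
analysis$stats$mw_ivs
plot_stress_stretch(analysis$summaries$circumferential)
write_analysis(analysis, "arterymech_out")
```

The written bundle contains tidy CSV tables (per-sample IVS and QC, curves,
tangent moduli, group summaries), the statistics as JSON, a markdown run
report, and a `manifest.json` hashing every artifact together with the
configuration, seed and package version, so a run can be re-verified file
by file.
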