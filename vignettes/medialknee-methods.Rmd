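---
title: "Modelling medial knee cartilage loading and lifetime failure risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling medial knee cartilage loading and lifetime failure risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medialknee)
```

## The problem

Medial tibiofemoral osteoarthritis is strongly mechanically mediated:
the inner compartment of the knee carries most of the joint load during
walking, and gait modifications (toe-in, toe-out, lateral wedge
insoles) are studied as conservative ways to unload it.  `medialknee`
implements the desk-side part of that research chain.  Given per-trial
gait features — peak medial compressive force (in multiples of body
weight), knee flexion angle at the instant of peak force, stride
length, and walking context — it computes cartilage contact stress and
strain with an elastic-foundation model, projects a lifetime
probability of cartilage fatigue failure with a competing biological
repair process, and compares gait conditions with the repeated-measures
statistics appropriate to within-participant designs.  A synthetic
cohort generator stands in for the motion-capture and musculoskeletal
simulation front end, which is out of scope.

## Elastic-foundation contact model

The medial compartment is idealised as a rigid femoral condyle pressed
into a bed of independent nonlinear springs (the cartilage) resting on
a rigid tibial plateau.  The condyle has two convex sagittal arcs —
anterior (35.0 mm) and posterior (18.9 mm) — and one frontal arc
(20.0 mm); the plateau is concave in both planes (frontal 21 mm,
sagittal 37.0 mm).  Which sagittal arc is engaged depends on the knee
flexion angle through a simple threshold (default 30 degrees): the
flatter anterior arc governs early-stance postures, the tighter
posterior arc deep flexion.  The engaged-arc selection is deliberately
a step function rather than a tangency construction; it is the one
place where the model responds discontinuously to an input, and the
transition angle is exposed in `knee_geometry()`.

Each element of a regular grid (default 111 x 66 elements at 0.5 mm
spacing, 7326 springs) is compressed by whatever interpenetration the
rigid surfaces prescribe.  With compression `delta` and unloaded
thickness `h` (5.0 mm), the element strain is `eps = delta / h` and the
element stress follows the logarithmic spring law

```
sigma = -E * ln(1 - eps)
```

which stiffens without bound as the element approaches full
compression.  `E` is an effective modulus combining the femoral layer
(8.6 MPa) with the tibial layer beneath it: 10.1 MPa where the meniscus
covers the plateau (46% of elements, assigned from the periphery
inward, matching the meniscus' ring-like footprint) and 4.0 MPa in the
uncovered centre.  The default combination rule treats the two layers
as springs in series (harmonic mean); arithmetic-mean and tibial-only
rules are selectable in `cartilage_material()` because the literature
is not explicit about the averaging.  The meniscus' own modulus
(1.3 MPa) and the Poisson ratio (0.45) are carried as metadata: an
independent-spring foundation has no lateral coupling and no meniscal
load path, so neither quantity enters the force balance.

Loading is applied exactly the way the physical procedure is described:
the femoral surface starts at the height where every spring is just
unloaded, then the flexion axis is lowered until the summed spring
force matches the target medial force.  Because total force is strictly
increasing in axis depth, bisection brackets the unique solution; the
default force tolerance is 0.5 N and solutions are typically found in
30-60 iterations.  `solve_contact()` returns the full compression,
strain and stress fields plus the summary scalars used downstream: peak
stress, peak strain, loaded area, and stressed volume (loaded area
times unloaded thickness).

### Calibration of the unprinted geometry

Two radii of this model family are not tabulated anywhere we could
find: the femoral frontal radius and the sagittal concavity of the
tibial plateau.  The frontal pair (20 mm femur inside a 21 mm tibia)
follows the convention that perfect conformity would be degenerate —
the whole width would engage at once.  The tibial sagittal radius
matters much more.  A sagittally flat plateau concentrates contact in a
narrow anteroposterior band and, at the reference cohort-mean load
(2.68 BW for a 69.31 kg adult), drives peak strains near 0.44 — twice
the strains this model family reports.  We therefore calibrated the
sagittal concavity once, before any tests were written, so that the
model maps that reference load to the reference peak strain of about
0.22; the resulting 37.0 mm is slightly less conforming than the
35.0 mm anterior femoral arc and sits inside the anatomical range
reported for the medial plateau.  It is a model constant, not a fitted
per-dataset parameter, and `knee_geometry(tibial_sagittal_radius = Inf)`
recovers the flat-plateau variant.

## Weibull failure model with repair

Cartilage fatigue is modelled as a Weibull cumulative-damage process
driven by the peak compressive strain and the daily number of loading
cycles.  The time to failure — the time at which 63.2% (1 - 1/e) of
samples would fail under the imposed strain — is

```
t_f = c_p * (time per cycle) * (c_w * eps)^(-b)
```

with power-law coefficient `c_p = 1.0`, Weibull coefficient
`c_w = 1.03` and power-law exponent `b = 12.9`.  The time per cycle
comes from a daily walking distance of 6.0 km: by default each of the
two steps per stride loads the joint once (`cycle_count = "steps"`,
about 7000 cycles/day at a 1.71 m stride, matching the common
7000-steps-per-day benchmark); counting strides instead is available by
flag and exactly doubles `t_f`.  The exponent makes the model
exquisitely sensitive to strain — a 10% strain increase shortens `t_f`
by a factor of about 3.4 — which is why per-participant failure
probabilities are strongly right-skewed even for modest gait
differences.

Failure probability follows the weakest-link form

```
P(t) = 1 - exp(-(V / V_ref) * (t / t_f)^(k / b))
```

with Weibull exponent `k = 14.3` and reference stressed volume
`V_ref = 78.5` mm^3 (the volume of the cylindrical explants behind the
fatigue constants).  Repair is a competing Weibull process,
`P_r(t) = 1 - exp(-(t / 5.0)^5.2)`, whose time constant means 63.2% of
damage cases recover within five years.  The repair-adjusted failure
probability integrates the exact failure density weighted by the
probability that repair has not yet occurred,

```
P_rep(T) = integral_0^T f(t) * (1 - P_r(t)) dt
```

by the trapezoidal rule on a 0.01-year grid over a 37-year horizon
(skeletal maturity at 18 to the median osteoarthritis diagnosis age of
55).  The printed form of the density in the source literature is
typographically inconsistent; the implementation uses the exact
derivative of the cumulative law, which quadrature-checks against the
closed form to 1e-4 and against an independent Monte-Carlo
failure/repair sampler to 5e-3.

Two conventions are shipped for the repair survivor term.  The default
evaluates it at absolute time `t`, following the literal description of
the procedure; the alternative (`repair_reference = "since_damage"`)
convolves it with the age of the damage, `1 - P_r(T - t)`, and measures
"failed and not yet repaired", a quantity that may legitimately decline
as old damage heals.

### The stressed-volume convention

The weakest-link prefactor `V / V_ref` deserves an explicit design
note.  The geometric stressed volume of a physiological contact patch
in this model (loaded area times thickness) is of order 5000-9000 mm^3,
a ratio of ~100 against `V_ref`; feeding that ratio into the cumulative
law saturates the 37-year failure probability near 100% for every
condition, which is inconsistent both with the lifetime-risk scale this
model family reports and with epidemiological incidence at age 55
(~9-13%).  The package therefore defaults to evaluating failure for an
explant-equivalent volume (`volume_rule = "reference"`, V = V_ref),
i.e. the risk that a reference-scale tissue sample embedded at the peak
strain site fails; the geometric convention remains available as
`volume_rule = "loaded"`.  The contact solution always reports its
geometric `stressed_volume` regardless of this choice.

## Synthetic cohort generator

`generate_cohort()` emulates a 15-participant, 4-condition (neutral,
toe-in, toe-out, lateral wedge insoles), 5-trial repeated-measures
study.  Per-condition means and SDs of the seven features default to
the reference cohort's summary statistics; knee flexion at peak force
is not among the published summaries, so its default (18 +/- 4 degrees,
identical across conditions) is typical early-stance flexion at the
first force peak.  Each feature decomposes into a participant random
intercept (SD = 0.7 of the feature SD, shared across conditions) plus
trial noise (SD = sqrt(1 - 0.7^2) of the per-condition SD), giving a
within-participant correlation of about 0.49 across conditions.  The
0.7 split is an assumption — the published summaries contain no
correlation information — and is exposed as
`between_participant_sd_fraction`.  Features are mutually independent
given the intercept, Gaussian, and truncated at physical bounds
(positive forces and strides, peak force at least the stance mean) by
redrawing offending trials.

What the generator does *not* emulate matters for interpreting green
tests: there are no waveforms (only one straight-line centre-of-pressure
fixture for the progression-angle estimator), no
participant-by-condition interactions, no feature covariances beyond
the shared intercept, and no muscle-level or metabolic outputs.
Passing end-to-end tests therefore demonstrates that the computational
chain is faithful and statistically calibrated under these idealised
conditions, not that it reproduces any individual's measured gait.

## Statistics stage

Condition comparisons follow the repeated-measures recipe: trials are
averaged to participant x condition means first, then a linear
mixed-effects model with a participant random intercept (REML; the
random intercept induces compound symmetry) is fitted per outcome, and
all six pairwise contrasts are extracted with Satterthwaite degrees of
freedom (`lmerTest` / `emmeans`; this stage deliberately delegates to
those established fitters).  Effect sizes are paired Cohen's d — mean
difference over the SD of the paired differences — because
within-subject designs produce large standardised effects from
differences that look small against cross-sectional SDs.  No
multiplicity correction is applied by default, matching common practice
in this literature; `adjust = "holm"` is available.  Singular or failed
fits fall back to paired t-tests with a warning.  On null cohorts the
contrast-level type-I error calibrates to the nominal 5% (checked over
1000 simulated null cohorts).

## Numerical choices and problem sizes

* Contact bisection: force tolerance 0.5 N, bracket from the unloaded
  height to just below full compression of the deepest element;
  residuals are checked in every test.  A single solve on the default
  mesh takes a few milliseconds.
* Failure integration: trapezoidal rule, 0.01-year step (3701 grid
  points over 37 years); halving the step changes terminal
  probabilities by less than 1e-4.
* Grid convergence: halving the element spacing to 0.25 mm changes peak
  stress by under 2% at the reference load.
* Filtering: 4th-order zero-lag Butterworth, applied forward and
  backward with odd reflection padding and steady-state initial
  conditions so that passband identity holds to numerical precision at
  the signal edges.
* Test and replication sizes: the test suite uses 20 end-to-end
  replicate cohorts (15 x 4 x 5 trials each) for ordering recovery and
  1000 null cohorts for type-I calibration; the cohort-calibration
  checks use up to 10,000 synthetic participants.  These sizes were
  chosen to keep Monte-Carlo error comfortably below the tolerances
  being asserted.

## Known limitations

* The contact model is quasi-static, medial-compartment only, with no
  translational femoral kinematics, no finite-element continuum
  mechanics, and no meniscal load sharing or hoop stresses.
* The arc-transition threshold makes strain a discontinuous function of
  flexion angle near the transition; trials generated near 30 degrees
  of flexion can produce posterior-arc strain outliers.
* The failure constants are borrowed from explant fatigue data; no
  biological covariates (inflammation, adiposity) are modelled, and the
  repair process assumes complete restoration of repaired damage.
* Walking velocity and stride length are consumed as precomputed
  scalars; the package performs no kinematic joint-angle computation
  and reads no C3D/motion-capture formats.
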