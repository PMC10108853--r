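---
title: "From ultrasound architecture and dynamometry to muscle force: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ultrasound architecture and dynamometry to muscle force: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archforce)
```

`archforce` estimates the contractile properties of a single muscle (the
vastus lateralis serves as the reference case throughout) from two
in vivo measurement streams: isokinetic/isometric dynamometry and
ultrasound-based fascicle geometry. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, what
the synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. From torque to muscle force

A dynamometer trial is a sampled `(time, knee-flexion angle, torque)`
trace; angles are in degrees with 0° = full extension. Conditioning has
three steps.

**Filtering.** `filter_torque()` applies a second-order Butterworth
low-pass (default cutoff 20 Hz) forward and backward, so the phase is
exactly zero and the effective magnitude response is the squared
Butterworth magnitude — gain 1 at DC and exactly 1/2 at the cutoff.
Edges are handled by odd-reflection padding of about three filter time
constants (`3·fs/cutoff` samples) combined with steady-state initial
conditions, so a constant trace passes through bit-exactly and smooth
traces show no start-up transients. A shorter pad (a few samples) cannot
absorb the ~50 ms transient of a 20 Hz filter at 1000 Hz sampling, which
is why the pad is tied to the filter time constant rather than the filter
order.

**Peak-preserving variant (twicing).** A zero-phase low-pass attenuates a
smooth in-band transient of "rate" $a$ (the local exponential/Gaussian
time scale) by $\mathcal{O}((a/\omega_c)^4)$ — a fraction of a percent for
a knee extension at 400 °/s, which matters once that peak force enters an
ill-conditioned curve fit (Section 3). `filter_torque(..., twicing = k)`
therefore offers Tukey's twicing / van Cittert iteration: with smoother
$S$, the operator $I - (I - S)^{k+1}$ adds the smoothed residual back $k$
times, cancelling $k$ further orders of attenuation while still rolling
off out-of-band noise. The pipeline reads isokinetic peak forces with
`k = 3` (config `peak_twicing`); everything else uses the plain filter.

**Passive correction.** The torque of a slow passive movement contains
the limb's gravitational moment plus passive elastic torque; both are
functions of angle, not time. `correct_passive()` interpolates the
passive torque at the active trial's angles and subtracts — one
subtraction handles gravity and passive tissue together.

**Force.** Knee extension force is τ / r(θ). The moment arm r(θ) is a
configurable polynomial; the shipped default
`0.035 + 3.5e-4·θ − 3.5e-6·θ²` m (θ in degrees flexion) is positive and
single-peaked over 0–110°, spanning 3.1–4.4 cm, consistent with published
patellar-tendon moment arms. Because the source studies of such models
differ by several millimetres, all forces scale with this choice, and the
model is deliberately a parameter, not a constant. A single muscle's
share is its physiological cross-sectional area fraction; the default
0.35 matches the ratio of a literature cohort's mean vastus lateralis
fascicle force to its mean knee-extension force (1856/5295 ≈ 0.3506).

**Isometric plateau reading.** Isometric trials follow a ramp-and-hold
protocol. The plateau value is the mean corrected torque over the final
hold (`iso_hold_s`, default 2.5 s), and the fascicle length is the median
of the raw frames in the same span. The pointwise maximum of a flat noisy
plateau is biased upward by the order statistics of the noise (≈ +0.5%
under 2 N·m torque noise), and the force-length fit propagates that bias
into every downstream force parameter — the hold mean is unbiased and
exact in the noiseless limit.

## 2. Fascicle geometry

All geometry is planar, matching B-mode imaging: x along the muscle's
line of action (proximal positive), y = depth (superficial positive).
Aponeuroses and fascicle segments are reduced to total-least-squares
lines (principal axis of the point cloud), which is robust to
segmentation jitter along the feature.

*Dual-probe mode.* Two transducers in series, the distal one the
reference frame and the proximal one offset by the holder gap and tilted
by the holder's angulation (default 5°), are fused by rigid transforms
(`fuse_probe_frames()`), which provably preserve lengths and angles. The
fascicle is extrapolated linearly from its deep insertion (intersection
with the deep aponeurosis line) to the superficial aponeurosis line
(`extrapolate_fascicle_length()`); when both fields of view provide a
superficial aponeurosis, both candidate lengths are computed and the
shortest wins (`shortest_candidate_length()`), the conservative rule for
contracted fascicles that do not span the inter-probe gap. Pennation is
always measured against the deep aponeurosis; thickness is the mean
inter-aponeurosis distance over a region of interest, measured
perpendicular to the deep aponeurosis.

*Panoramic mode.* Extended-field-of-view scans yield fragment
orientations rather than whole fascicles. `composite_fascicle_panoramic()`
anchors a curve on the deep aponeurosis and integrates a composite
fascicle whose inclination blends linearly (in the depth fraction)
between the dominant deep and superficial orientations; fascicle length
is the arc length between aponeuroses. For equal orientations the
composite is exactly the straight line of length `thickness/sin(angle)`;
for differing orientations the arc length always lies strictly between
the two straight-line candidates. Integration uses 4000 explicit steps
with an interpolated final partial step; straight composites are exact by
construction, and the step count only matters for curved ones (relative
error well below the segmentation noise floor).

## 3. Contractile models

**Force-length.**
$F(L) = F_{max}\,\exp(-\lvert((L/L_0)^b - 1)/s\rvert^{\rho})$, with
skewness $b$, width $s$ and shape exponent $\rho = 2$ by default
(configurable; the curve peaks at exactly $L = L_0$ for any $\rho > 0$).
As $L \to 0$ the model plateaus at $F_{max} e^{-(1/s)^\rho}$ rather than
reaching zero — a property of this parameterisation worth knowing when
extrapolating far below optimal length. The fit is bounded
Levenberg-Marquardt over $(F_{max}, L_0, b, s)$ with data-driven starts
($L_0$ at the strongest measured length, $F_{max}$ at 1.05× the largest
force, $b = 1$, $s = 0.5$). Six isometric angles straddling the optimum
identify all four parameters; the fitted $F_{max}$ legitimately exceeds
every observation when the true peak falls between tested angles.

**Force-velocity.**
$F(v) = F_{max}(1 - v/v_{max})/(1 + G\,v/v_{max})$ on $0 \le v \le
v_{max}$, shortening positive. $F_{max}$ is fixed from the force-length
fit; $G$ is constrained to $(3, 9)$ by hard box bounds with a $10^{-6}$
margin ("allowed" curvature read as optimizer bounds), and a solution
within $10^{-4}$ of a bound is flagged (`bound_hit`), never an error —
with measured velocities reaching only ~20% of $v_{max}$, bound hits are
an expected symptom of the pair's weak identifiability, not a failure.
$v_{max}$ is unconstrained above the fastest observation.

Two numerical choices matter here:

* *Optimization.* The $(v_{max}, G)$ least-squares surface is a long
  curved valley; plain Levenberg-Marquardt from a fixed start can stall
  against the curvature bound even on exactly-representable data. The
  fit therefore profiles $G$ on a grid, minimising over $\log v_{max}$
  by 1-D golden-section for each, and polishes the best profile point
  with the bounded 2-parameter fit. On noise-free data this recovers
  parameters to machine precision across the whole band.
* *Weighting.* Measurement uncertainty differs strongly between speeds
  (the 400 °/s window is 75 ms; the 50 °/s window is 600 ms). The
  pipeline runs a two-stage fit: an ordinary fit supplies the local curve
  slope, each point then gets an effective variance
  $\sigma_F^2 + (\partial F/\partial v)^2 \sigma_v^2$ built from
  data-driven noise estimates (torque noise from the high-frequency
  filter residuals, frame noise from the Savitzky-Golay smoothing
  residuals, converted through the slope-estimator's design variance),
  and the fit is repeated with inverse-effective-variance weights.
  Weights cannot move an interpolating solution, so the noiseless closed
  loop is untouched.

**Derived measures.** `force_iso400` is the *measured* peak force of the
fastest condition, not a curve value. `force_slope` is the decline in
normalised force between the fitted curve evaluated at the slowest and
fastest measured velocities, per velocity unit; since the printed unit of
this quantity in the literature is ambiguous, the summary reports it both
per cm/s and per optimal-length/s (the two differ by the factor
$L_0/10$).

## 4. Kinematics

Fascicle velocity is defined by central differences (shortening
positive); `fascicle_velocity()` implements exactly that and is the right
tool for smooth tracked series. For frame-wise noisy segmentations the
pipeline instead uses the Savitzky-Golay local-quadratic derivative with
a span of 1.5× the iso-velocity phase duration: it is exact wherever
length is locally quadratic in time — in particular on the
constant-velocity phase — and a local slope whose span crosses a velocity
kink always lies *between* the two segment slopes, so the windowed peak
still comes from kink-free centres. Differencing a smoothed series is
roughly four times noisier than the direct S-G derivative, which is why
the latter is the default.

The iso-velocity window (80°–50° flexion, the constant-velocity phase
common to all speeds) is located by linear interpolation of the angle
crossings, first extension crossing on ripples. Peak force and peak
velocity are each their own maximum within the window (they need not be
simultaneous). Peak force gets a parabolic sub-sample refinement, bounded
to a ±1-sample vertex shift so it cannot amplify noise; peak velocity
does not — the velocity profile in an iso-velocity phase is flat-topped,
where a parabolic vertex is meaningless.

## 5. Work

Joint work is the trapezoidal integral of torque over angle (radians)
across the window, endpoints interpolated exactly at the window angles,
which makes work additive across sub-windows. Muscle work integrates
single-muscle force over muscle length (fascicle length × cosine of
pennation), on the torque time base with the fascicle state linearly
interpolated onto it. Signs: extension torque during extension, and
shortening under tension, are positive.

## 6. The synthetic cohort

`generate_cohort()` draws participants from truncated-normal ground-truth
distributions whose means and SDs follow printed cohort statistics for
healthy adults (maximum knee-extension force 5295 ± 1504 N, optimal
fascicle length 105 ± 17 mm, $v_{max}$ 17.5 ± 10.5 $L_0$/s, G 6.1 ± 2.7
truncated inside (3, 9), and condition-wise architecture close to
82.3 ± 9.5 mm / 15.7 ± 2.4° at full extension at rest, 120.4 ± 12.7 mm /
10.9 ± 1.6° at 60° at rest, 96.7 ± 18.1 mm / 14.5 ± 2.7° during MVC at
60°). Pennation co-varies with strength and condition-wise length with
optimal length (correlation 0.6), so cohort-level architecture-force
correlations are present to be found. Thickness is derived as
$L \sin\theta$ for straight-fascicle consistency, which shifts thickness
means ~1 mm from typical printed values — real fascicles curve, synthetic
ones do not.

Each participant gets six isometric trials (100°–50°, ramp-and-hold with
a C¹ activation ramp so the filter sees no corner), five isokinetic
trials (110°→0° at 50–400 °/s with activation complete before the
dynamometer releases, as in an isokinetic pre-loading protocol), and one
passive movement (smooth exponential elastic torque plus a gravity term).
Simulated torque is the passive component plus the participant's
force-length × force-velocity surface evaluated at the simulated fascicle
state, times the moment arm, plus white Gaussian noise (defaults:
2 N·m torque, 1 mm fascicle length, 0.5° pennation per frame).

The fascicle-length/knee-angle mapping under contraction is
$L(\theta) = L_0(1 + 0.00795(\theta - 60))$: optimal length at the 60°
test angle, and a measured peak shortening velocity of ~3.2 $L_0$/s at
400 °/s — which together with the distribution means for G and $v_{max}$
reproduces the observed ratio of fastest-condition force to maximum force
(~0.39). Sampling rates default to 1000 Hz for torque and 100 Hz for the
fascicle series; two frames inside a 75 ms window cannot support velocity
estimation, so a frame rate typical of segmented high-frame-rate B-mode
sequences was chosen over slower conventional cine rates.

What the generator does **not** emulate: activation dynamics and torque
rise times (plateau and peak analyses only), series-elastic stretch
(fascicle velocity is angle-velocity-proportional inside the motion),
fascicle curvature, 3-D fascicle paths, history dependence of force, and
dynamometer angle noise. Passing closed-loop tests therefore validates
the estimation chain under the model's own assumptions; they say nothing
about, e.g., tendon compliance effects in real recordings.

## 7. Validation design

Two complementary checks gate the pipeline (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* *Noiseless closed loop* (n = 21): every participant's $F_{max}$,
  $L_0$, $v_{max}$ and G must return to better than 0.1%. This is what
  motivated the twicing peak reading: with the plain 20 Hz filter, peak
  attenuation of order $10^{-3}$ at 400 °/s is amplified 10-70× by the
  $(v_{max}, G)$ valley and breaks the loop.
* *Noise replicates*: 200 simulations of a fixed representative
  participant (ground truth at the distribution means) under 2 N·m /
  1 mm noise; the median absolute curvature error stays below 0.5.
  Replicating a fixed participant isolates estimator error from cohort
  heterogeneity; participants drawn near the upper $v_{max}$ truncation
  have close to unidentifiable curvature at these measured velocities,
  which is the same phenomenon that makes G the noisiest quantity in
  in vivo studies.

Problem sizes used throughout (21 participants, 200 replicates, 1000-draw
geometry sweeps) were chosen as the smallest that make the checks
statistically meaningful.

## 8. Statistics

Pearson correlations are computed per pair on complete cases with
two-sided p-values on n − 2 degrees of freedom; significance is α = 0.05
without multiple-testing correction (a Holm-adjusted column is emitted
alongside, clearly separate). Strength classification uses |r|: ≥ 0.7
strong, [0.4, 0.7) moderate, < 0.4 weak — so strong negative correlations
classify as strong. The normality screen defaults to the Lilliefors
variant (Kolmogorov-Smirnov with estimated mean and SD, valid p-values,
n ≥ 5); the plain KS test against the fitted normal is available and
flagged approximate. Screens are reported, never used to switch methods
silently.

## 9. Limitations

* Moment arm and PCSA share come from literature models, not from the
  individual; absolute forces inherit their uncertainty (relative
  comparisons within a cohort are unaffected by the shared scale).
* G and $v_{max}$ are weakly identified when $v_{max}$ far exceeds the
  fastest measured fascicle velocity; expect bound hits and wide spreads
  (that is the message of the noise-replicate numbers, not an artifact).
* The geometry is 2-D; out-of-plane fascicle paths bias lengths in ways
  the package cannot detect from coordinates alone.
* `read_supplementary_table()` maps third-party per-participant tables
  through a user-supplied codebook; the shipped example table is a
  synthetic stand-in generated by this package, not study data.
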