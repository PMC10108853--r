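# archforce

Linking skeletal muscle architecture to in vivo force production.

`archforce` is an R package for researchers in muscle physiology and
biomechanics who measure vastus lateralis architecture with B-mode
ultrasound (fascicle length, pennation angle, muscle thickness) and muscle
function with an isokinetic dynamometer, and want to relate the two. It
implements the full analysis chain from raw recordings to cohort-level
correlation tables, together with a synthetic-cohort generator with known
ground truth that lets every stage be validated by closed-loop parameter
recovery.

## The analysis

**Torque to muscle force.** Knee-extensor torque is low-pass filtered with
a second-order bi-directional Butterworth filter (cutoff 20 Hz, zero
phase), corrected by subtracting the torque of a passive movement matched
by joint angle (gravity + passive elastic torque), and converted to knee
extension force as τ / r(θ), where r(θ) is an angle-dependent moment-arm
model. A single muscle's force is its PCSA share of the total (default
0.35 for the vastus lateralis).

**Fascicle geometry.** Dual-probe segmentations are fused into a common
frame by rigid transforms; fascicles are extrapolated linearly to the
superficial aponeurosis, with the shortest-candidate rule across fields of
view. Panoramic scans are reconstructed as a composite fascicle whose
inclination blends between the dominant deep and superficial fragment
orientations; thickness is the mean inter-aponeurosis distance.

**Contractile models.** The active force–length relation

    F(L) = F_max · exp( −| ((L/L0)^b − 1) / s |^2 )

is fitted to the six isometric plateaus (100°–50° knee flexion), giving the
theoretical maximum force `F_max` and optimal fascicle length `L0`. Peak
fascicle shortening velocities and peak forces measured in the iso-velocity
phase (80°–50°) of the five isokinetic trials (50–400 °/s) are then fitted
with the Hill hyperbola

    F(v) = F_max · (1 − v/v_max) / (1 + G·v/v_max),

with the curvature constrained to 3 < G < 9 and `v_max` free. Derived
measures: the measured force of the fastest condition (`force_iso400`) and
the normalised force–velocity slope between the slowest and fastest
measured velocities (`force_slope`). Joint and muscle work are trapezoidal
integrals over the common iso-velocity phase.

**Statistics.** Pearson product–moment correlations (n − 2 degrees of
freedom) between architecture and force/work variables, classified strong
(|r| ≥ 0.7), moderate (0.4 ≤ |r| < 0.7) or weak (|r| < 0.4), with a
Lilliefors normality screen and mean ± SD summary tables.

## Worked example

```r
library(archforce)

cohort <- generate_cohort(simulation_config(n_participants = 21, seed = 42))
result <- run_pipeline(cohort)
print(result)
#> <pipeline_result> 21 participants
#>   force_max 5757 +/- 1652 N | force_iso400 2758 +/- 991 N
#>   L0 105.4 +/- 16.5 mm | G 5.40 +/- 1.73 | vmax 21.6 +/- 4.7 L0/s
```

The cohort means land where a healthy adult cohort should: a theoretical
maximum knee-extension force of a few thousand newtons, optimal fascicle
lengths around 105 mm, and a force–velocity curvature G in the middle of
its physiological band. Because the cohort is synthetic, the estimates can
be compared against the generating truth:

```r
err <- recovery_errors(result)
signif(max(err$rel_err_force_max), 3)   # 0.00509  (0.5% under noise)
signif(median(err$abs_err_G), 3)        # 0.602    (curvature is hardest)
```

With measurement noise switched off (`noise_torque_sd = 0`,
`noise_length_sd = 0`, `noise_pennation_sd = 0`) all four contractile
parameters return to better than 0.1% — the closed loop that validates the
whole chain. The correlation table reads like this:

```r
head(result$correlations[order(-abs(result$correlations$r)), ], 3)
#>             var_x     var_y     r        p strength
#>  pennation_rest60 force_max 0.859 6.14e-07   strong
#>   thickness_mvc60 force_max 0.664 1.03e-03 moderate
#>  thickness_rest60 force_max 0.652 1.36e-03 moderate
```

i.e. in this synthetic world — where thickness and pennation are generated
to co-vary with strength — the pipeline finds exactly that, while fascicle
length correlates with the work variables instead.

Per-participant fits are ordinary objects:

```r
result$fits[[1]]$fl
#> Force-length fit: force_max = 7360.9 N, L0 = 95.5 mm, b = 1.580, s = 0.489 (rho = 2, RSS = 141)
result$fits[[1]]$fv
#> Force-velocity fit: vmax = 1.9e+03, G = 5.141 (force_max fixed at 7360.9 N, RSS = 1.03e+03)
```

Cohorts can be written to and re-read from plain CSV directories
(`write_cohort()`, `read_cohort()`, one file per trial plus a JSON
manifest), and per-participant summary tables in third-party layouts load
through a codebook with `read_supplementary_table()`; a synthetic example
table ships in `inst/extdata/`.

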