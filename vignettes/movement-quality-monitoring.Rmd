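---
title: "Monitoring home task-practice movement quality with a wrist-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring home task-practice movement quality with a wrist-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stroke survivors are prescribed repetitive upper-limb task practice at home,
but practicing with compensatory movement patterns (trunk flexion instead of
reaching, shoulder hike instead of lifting, whole-hand instead of precision
grip) reinforces maladaptive strategies. A single 9-axis inertial
measurement unit (IMU) worn on the paretic wrist is one of the few sensors
patients reliably tolerate at home. `wristdtw` implements a
participant-specific pipeline that labels each home task repetition as
*correct* or *incorrect* by comparing it against a handful of
therapist-labeled reference repetitions recorded in the clinic:

1. **Preprocessing** — orientation and gravity estimation from accelerometer
   + gyroscope, gravity subtraction, channel assembly, optional per-axis
   normalization.
2. **Windowed multivariate DTW** — alignment of a test trial to a reference
   trial under a Sakoe–Chiba-style band, reduced to a test-anchored
   *projected distance*.
3. **Method selection** — a per-participant grid search over channel
   subsets, normalization, and window sizes, scored by a one-sided Welch
   test on distance clusters and leave-one-trial-out (LOTO) accuracy.
4. **Classification** — 1-nearest-neighbor quality labeling of each home
   trial, with confusion matrices, accuracy, F1, and per-movement-type
   sensitivity.
5. **Synthetic data** — a physically consistent rigid-body IMU simulator so
   the entire pipeline is testable end to end without any recordings.

Participant-specific modeling is the point: stroke survivors differ in
impairment and in the compensations they use, so the classifier never pools
across participants and never adds home trials to the reference set.

## Signal model and preprocessing

Each trial is a uniformly sampled (nominally 100 Hz) table of accelerometer
(m/s², sensor frame), gyroscope (rad/s) and magnetometer (µT) readings.
The accelerometer measures specific force: a level, motionless sensor reads
$(0, 0, +g)$ with $g = 9.80665\,\mathrm{m/s^2}$. Trials whose median
sampling interval deviates from nominal are linearly resampled; trials are
pre-segmented (segmentation of continuous streams is out of scope).

**Orientation filter.** The gravity direction is estimated with a six-axis
(accelerometer + gyroscope) filter: the gyroscope is integrated into a unit
quaternion, and the tilt is corrected toward the measured acceleration
direction with a fixed steady-state gain $k = \Delta t/(\tau + \Delta t)$,
$\tau = 0.5$ s by default. The correction is gated off when
$\lvert\,\lVert a\rVert - g\,\rvert > 0.2\,g$, so strong movement-induced
acceleration does not corrupt the tilt. The filter initializes from the
first sample's tilt (yaw is unobservable from gravity and irrelevant here,
since only the gravity vector and the gravity-free residual are consumed
downstream). We chose the fixed-gain formulation over a full error-state
Kalman filter because the testable contract is behavioral—static recovery
within 1° and rotating-trial tracking within 2° RMS—and a fixed-gain filter
meets it with two interpretable parameters instead of a covariance model
that the data could not identify anyway. The gravity estimate has exactly
magnitude $g$ by construction; `gravity + lin_acc` reconstructs the raw
accelerometer stream exactly.

**Channels.** Four derived channel groups are available, stacked in the
canonical order `lin_acc` (acceleration without gravity), `grav` (gravity
vector), `gyro`, `mag`. Normalization, when enabled, divides each axis by
its standard deviation (sample convention, $n-1$) computed over the
concatenation of the participant's *lab* trials only; the same scales are
applied to home trials. Lab-only scales keep home classification causal
with respect to the reference data — the alternative (pooling lab + home)
would let the home distribution leak into the references. Constant
channels get scale 1 with a warning rather than dividing by zero.

## DTW and the projected distance

For test trial $x_{1:T}$ and reference $y_{1:M}$ (rows = samples, columns =
channels), the local cost is the Euclidean distance between aligned rows,
the step set is $\{(1,1), (1,0), (0,1)\}$, and the path is constrained to
the band $|i - j| \le w$. DP ties are broken deterministically: diagonal
first, then the test-advancing step, so results are bit-reproducible.
When $|T - M| > w$ no monotone path exists; this is an explicit
*infeasible-window* condition, never a silent large distance.

Raw accumulated cost depends on path length, so trials of different
durations are not comparable. The pipeline therefore projects the warped
reference onto the test trial's time base: the reference samples matched to
each test index $i$ are averaged into $\bar r(i)$, and

$$d(x, y) = \frac{1}{T} \sum_{i=1}^{T} \lVert x(i) - \bar r(i) \rVert_2 .$$

Averaging matched samples (rather than summing) and averaging over test
length makes $d$ a mean per-sample discrepancy on the test clock; it is the
distance used everywhere downstream. $d = 0$ exactly when the projected
reference equals the test, and multiplying a single channel in both inputs
by $k > 0$ scales the single-channel distance by $k$.

The window grid is $w \in \{50, 100, 200, 300, 400\}$ samples (0.5–4 s at
100 Hz, five roughly log-spaced points covering the stated range). Windows
larger than the longest trial are equivalent to an unconstrained band and
are deduplicated internally.

## Method selection

A *method* is a triple (channel subset, normalize?, window). The default
grid crosses all 7 nonempty subsets of `{lin_acc, grav, gyro}` with
normalization on/off and the five windows (70 methods). The magnetometer is
excluded by default because it encodes heading relative to the earth's
field, which differs between lab and home environments and therefore
carries setting rather than movement information; `include_mag = TRUE`
restores it for exploration.

For each method and each unordered pair of movement types with differing
quality labels, two distance clusters are formed from the lab references:
*within* (all directed distances inside each of the two types, self-pairs
excluded, pooled across the two types) and *between* (both directions
across the types). A one-sided Welch (unequal-variance) two-sample $t$-test
evaluates whether within-type distances are smaller; the **maximum**
p-value over all such pairs ($p_{\max}$) summarizes the method — it is
small only if *every* cross-quality contrast separates. Welch rather than
pooled-variance because the two distance clusters have no reason to share a
variance; zero-variance degenerate clusters fall back to a direct mean
comparison (p = 0 if the within mean is smaller, else 1). No
multiple-testing correction is applied across grid cells: the p-values
rank methods, they are not inferential claims.

Selection then proceeds in documented stages: (1) drop methods infeasible
for any lab pair; (2) keep methods with $p_{\max} < \alpha$ (default 0.05),
or, if none pass, the argmin of $p_{\max}$; (3) keep those with maximal
LOTO accuracy, where each lab trial is 1-NN classified against the other
trials of its own task and scored at the quality (correct/incorrect)
level — quality, not movement type, because quality is what the pipeline
ultimately outputs; (4) remaining ties prefer `lin_acc+grav+gyro` with
normalization, then the larger window, then the canonical grid order. Every
stage is logged in a selection trace. With several tasks, $p_{\max}$ is
taken over all tasks' type pairs and LOTO pools tasks, yielding one method
per participant.

## Classification and reporting

Each home trial (as test) is aligned to every lab reference of its task;
the quality label of the reference with the minimum projected distance is
assigned. Distance ties go to the earlier reference in session order.
Trials for which *every* reference is window-infeasible are flagged
unclassifiable, reported, and excluded from the matrices — never silently
dropped or silently scored.

Reports contain the overall confusion matrix, per-task matrices (which sum
cell-wise to the overall), accuracy, $F_1 = 2TP/(2TP + FP + FN)$, and
per-movement-type sensitivity (fraction of true-incorrect trials of each
annotated type predicted incorrect). The positive class for $F_1$ is the
*correct* movement: home practice is predominantly correct, and
sensitivity/F1 phrased on the correct class is the consistent reading of
the feasibility framing this pipeline follows.

**Acceleration-only ablation.** To quantify what the gyroscope buys (its
cost is battery life), `ablation_compare()` reruns selection and
classification restricted to channels derivable from the accelerometer
alone. Since the six-axis filter needs a gyroscope, the ablation estimates
gravity instead with a zero-phase second-order Butterworth low-pass at
0.5 Hz — the standard accelerometer-only gravity/body split. On scenarios
whose classes differ only in angular velocity, the ablation collapses to
chance while the full pipeline stays near perfect.

## The synthetic generator

`simulate_trial()` builds a rigid-body wrist trajectory from a parametric
template: each Euler angle (ZYX) is a minimum-jerk ramp plus a symmetric
bump over normalized time, and translation follows a minimum-jerk
displacement with an optional raised-path bump. From the analytic rotation
$R(t)$ and world acceleration $a(t)$ it emits exactly consistent sensors:
accelerometer $R^\top(a + g\hat z)$, gyroscope = body angular rates from
the closed-form Euler-rate transformation, magnetometer = a 50 µT field at
60° inclination rotated into the sensor frame, with a configurable yaw
offset between lab and home emulating the heading change that makes the
magnetometer unreliable across settings. Inter-trial variability: Gaussian
duration jitter, a multiplicative amplitude factor, and a smooth monotone
time warp $s \mapsto s + \varepsilon\sin(\pi s)$ applied with exact chain-rule
derivatives, so zero-noise signals remain exactly consistent with the
underlying motion. Noise: white accelerometer/gyroscope/magnetometer noise
and a gyroscope bias random walk at consumer-MEMS magnitudes
(0.05 m/s², 0.005 rad/s, 1e-4 rad/s·√s, 0.5 µT).

Compensatory variants are template modifiers: trunk/shoulder involvement
adds a pitch ramp and roll offset with a raised path; shoulder abduction a
roll offset and higher lift; compensatory grip a faster, larger-amplitude
translation with extra wrist extension; incomplete movements truncate the
trial at a random fraction; nonparetic-hand assist scales the paretic-wrist
motion to near-stationary. Study-design defaults are fixed once: 4 tasks,
2 movement types per task in the lab with 6 trials per quality (within the
3–6 feasible in a therapy session), 75 home trials per task, 80% of home
trials correct, and per-trial seeds derived from one root seed with a
counter so any subset regenerates identically.

**What passing synthetic tests does and does not show.** The generator
produces smooth, low-dimensional, well-separated movements; real paretic
movement is noisier, less stereotyped, and drifts across a session. The
end-to-end accuracy on the default configuration (≈0.99 over seeds)
therefore validates the *pipeline mechanics* — physical consistency,
selection behavior, determinism, metric arithmetic — not the clinical
accuracy attainable on real recordings, and the package makes no claim
that the synthetic accuracy transfers.

## Numerical choices and degenerate inputs

- DP tie-break: diagonal, then test-advancing; selection and 1-NN ties go
  to the earlier trial in session order. All results are deterministic
  given inputs and seed.
- Standard deviations use the sample ($n-1$) convention everywhere.
- All-zero accelerometer → error (orientation unobservable); trials
  shorter than 0.5 s → error (filter cannot settle); constant channels →
  scale 1 with warning; zero-variance Welch clusters → mean comparison.
- Window-infeasible trial pairs make a method infeasible for selection;
  at classification time a home trial is unclassifiable only if every
  reference is infeasible.
- Filter warm-up is included in the distance computation (trials are
  whole-movement segments; trimming would change lengths); the first
  sample initializes the tilt so the transient is small.

## Test problem sizes

The test suite exercises the exhaustive DTW oracle on 500 random pairs of
length ≤ 8, window monotonicity on 100 pairs over the full window grid,
gravity recovery on 50 static orientations and 20 rotating trials, Welch
calibration on 1000 null simulations, selection recovery on 20 seeded
replicates of a gyroscope-differentiated participant, and the end-to-end
study at its full default size (4 × 12 lab, 4 × 75 home) over 10 seeds —
sizes chosen to pin each property tightly while keeping a full run of the
suite within a few minutes on one core.

## Known limitations

- No segmentation of continuous recordings; trials arrive pre-cut.
- No nine-axis (magnetometer-fused) orientation and no adaptive filtering.
- Movement types absent from the lab references are scored against
  whatever references exist (and surfaced in the per-type table); the
  pipeline cannot flag "novel type" explicitly.
- The synthetic generator does not model skeletal kinematics, tremor,
  spasticity, or session-scale fatigue drift.
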