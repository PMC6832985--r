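---
title: "Methods: clinical movement features from a single lumbar IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical movement features from a single lumbar IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbargait)
```

`lumbargait` turns one lower-back (L5) inertial recording — triaxial
acceleration in g and triaxial angular velocity in deg/s, nominally sampled
at 31.25 Hz — into a fixed registry of 184 features describing three
standardized clinical tests: the 10 m Walk Test (10MWT) at self-selected
(SSV) and fast (FV) speed, the five static standing conditions of the Berg
Balance Scale (BBS), and the Timed Up and Go (TUG).  This vignette documents
the models behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic generators do and do not emulate, and
the known limitations.

## Preprocessing

Device timestamps jitter around the nominal rate, so every trial is first
linearly interpolated onto a uniform grid (`resample_uniform()`).

**Tilt correction.**  A sensor stuck to the lower back is never perfectly
aligned with the anatomical axes.  With the device's y axis near-vertical,
the tilt angles of its x and z axes relative to the horizontal plane are
estimated from the mean measured acceleration in g,
$\sin\theta_x \approx \bar a_x$ and $\sin\theta_z \approx \bar a_z$: over a
long window the dynamic components average out and only the gravity
projection remains.  By default the mean is taken over the whole annotated
trial; a static-window override is available when a known quiet segment
exists.  The accelerations are then rotated in two stages — first about the
tilt of the z axis using a provisional vertical channel
$\hat a_V = a_z\sin\theta_z + a_y\cos\theta_z$ and
$a_{AP} = -a_z\cos\theta_z + a_y\sin\theta_z$, then about the tilt of the x
axis, $a_{ML} = -a_x\cos\theta_x + \hat a_V\sin\theta_x$ and
$a_V = a_x\sin\theta_x + \hat a_V\cos\theta_x - 1$ — which removes the
static 1 g and yields anteroposterior (AP), mediolateral (ML) and vertical
(V) dynamic accelerations, converted to m/s² with g = 9.81 m/s².  For a
static sensor tilted up to 10° the residual mean acceleration after
correction is below 0.05 m/s² (the estimate of $\theta_z$ carries a
second-order error because gravity projects through $\cos\theta_x$).

**Axis convention.**  The two-stage rotation fixes the accelerometer
convention (y vertical, z posterior, x left–right at zero tilt), but the
gyroscope mapping to anatomical *pitch* (rotation about ML) and *yaw*
(rotation about V) depends on how the device is mounted; it is therefore a
configuration entry (`gyro_map`), defaulting to pitch = gx, yaw = gy with
positive signs, and the mapping of the abstract side labels A/B to left and
right feet is likewise configurable (`side_A_is`).

**Filtering.**  All filters are zero-phase (forward–backward Butterworth,
with odd-reflection end padding to suppress boundary transients): a 4th
order 10 Hz low-pass on the accelerations of walking tests — applied after
the coordinate transform — and a 4th order 2 Hz low-pass on yaw for
left/right assignment.  Zero-phase filtering matters because the whole
pipeline is built on event *times*; a causal filter would lag every contact
by a cadence-dependent amount.

## Gait events

Contacts are detected on the 10 Hz low-passed vertical acceleration
$a_V'$.  The series is integrated (cumulative trapezoid) and linearly
detrended, then differentiated by a continuous wavelet transform with the
first Gaussian-derivative wavelet; local minima of the result are initial
contact (IC) candidates.  Differentiating that output again with the second
Gaussian-derivative ("Mexican hat") wavelet gives a series whose local
maxima are end contact (EC) candidates.  The CWT acts as a smoothed
derivative, so the scale sets the smoothing bandwidth; it is chosen as
$s = F_c \, f_s / f_{dom}$, where $F_c$ is the wavelet centre frequency
(0.2 for the first derivative, 0.3 for the second) and $f_{dom}$ the
dominant cadence from the periodogram of $a_V'$ in 0.5–5 Hz.  The scale
rule is pluggable; any function of $f_{dom}$ can be substituted.

Candidate pruning applies three rules:

* EC candidates with magnitude at or below 20% of the mean candidate
  magnitude are discarded (`ec_min_frac`).
* The same relative gate is applied to IC minima (`ic_min_frac`, default
  0.2).  This is this package's own robustness addition: when the analysis
  window contains quiet stretches — as the TUG does between phases — CWT
  minima of pure sensor noise would otherwise become contacts.  On windows
  that contain only walking it retains every true minimum, since all
  candidate depths are comparable.  Setting `ic_min_frac = 0` restores the
  stricter reading in which only ECs are gated.
* An IC lagging the previous retained IC by less than 0.25 s or more than
  2.25 s is discarded.  Pruning is greedy left-to-right: the earliest IC is
  trusted.  Because the "more than 2.25 s" arm would cascade across any long
  event-free gap and erase everything after it, segmented trials (TUG) run
  the detector separately per walking/turning window (`tug_gait_events()`).

Events within 0.25 s of the window boundary are dropped (wavelet edge
effects).  Both relative gates are scale-free, so event times are invariant
to rescaling the input — amplitude units cannot change the detection.

Sides are assigned from the 2 Hz yaw: label A where yaw at the IC is
non-negative.  If more than 20% of consecutive pairs violate alternation,
labels are replaced by forced alternation phased to the majority.

Per-cycle temporal parameters follow the event-time definitions: stance
$T_{stance}(i) = t_{EC}(i{+}1) - t_{IC}(i)$, stride
$T_{stride}(i) = t_{IC}(i{+}2) - t_{IC}(i)$, step
$T_{step}(i) = t_{IC}(i{+}1) - t_{IC}(i)$, and swing
$T_{swing} = T_{stride} - T_{stance}$, which holds exactly by construction.
Step count is the number of ICs.

## Step length

The inverted-pendulum model treats the body's centre of mass as rotating
over the stance leg: a per-step change in height $h$ implies a step length

$$\hat L_{step} = 2\sqrt{2 L h - h^2},$$

with $L$ the pendulum length, measured as the distance from the sensor to
the ground.  $h$ is the peak-to-trough vertical displacement within each
step interval $[t_{IC}(i), t_{IC}(i{+}1))$; the alternative reading
(displacement difference between consecutive contacts) vanishes for
symmetric gait and was rejected.

Displacement comes from double integration of the vertical acceleration,
and raw double integration drifts.  Each integration therefore passes
through empirical mode decomposition: the integral is decomposed into
intrinsic mode functions, each component's Hurst exponent is estimated, and
components with $H > 0.8$ — trends, including the EMD residue — are removed
before re-summation.  The Hurst estimator is corrected rescaled-range
analysis (block R/S statistics over log-spaced window sizes compared with
their small-sample white-noise expectation); near 0.5 for white noise, near
1 for trends, near 0 for anti-persistent series, with a constant series
defined as 1.0 (a pure trend).  The raw uncorrected R/S slope overestimates
for white noise, which is why the correction is applied.  EMD uses standard
cubic-spline sifting with a Cauchy stopping criterion (tolerance 0.2, at
most 50 sifts per component) and mirrors the two extrema nearest each
boundary to curb end effects.  If decomposition yields no oscillatory
component the integral falls back to quadratic polynomial detrending with a
warning.

The pendulum estimate systematically misses a speed-dependent offset, fixed
by a calibrated correction $L_{step} = \hat L_{step} + K S$, with $S$ the
subject's shoe size and $K$ fitted per speed condition by least squares
against a gold standard, $K = (S^\top S)^{-1} S^\top (L^* - \hat L)$.  The
shipped defaults ($K = 1.13$ for SSV, $K = 1.50$ for FV) were calibrated on
a healthy cohort and **do not generalize**: impaired gait can reverse the
sign of the bias, so any new population needs recalibration via
`calibrate_K()`.  The units of $S$ are deliberately unconstrained — K
absorbs the shoe-size convention — but the convention must be identical
between calibration and application.  Step velocity is
$V_{step}(i) = L_{step}(i) / T_{step}(i)$.

## Static balance

Each BBS condition is summarized by 23 features of the unfiltered
gravity-removed AP/ML accelerations (no 10 Hz stage here: sway lives well
below it and the jerk feature would be distorted).

*Spectral* (per axis): the one-sided rectangular-window periodogram over
(0, Nyquist], DC excluded; F50% and F95% are the smallest frequencies
reaching 50% and 95% of cumulative power, and the spectral centroid is
$\sum f P(f) / \sum P(f)$.  No taper is applied: sway spectra are broad,
and the rectangular window keeps line-spectrum behaviour exact.  An
all-zero window reports missing spectral features rather than inventing a
value.

*Time-domain* (per axis, on the mean-subtracted signal): maximum and mean
absolute acceleration (rectified, since a zero-mean signed mean is
uninformative), RMS, jerk as the RMS of the central-difference derivative,
sway velocity as the mean absolute drift-free integral (same EMD facility
as step length), and the total acceleration path
$\sum_k |x(k{+}1) - x(k)|$, not normalized by duration.  All six are
homogeneous of degree one in signal amplitude.

*Ellipse*: the 2×2 AP/ML sample covariance is eigendecomposed; semi-axes
are $\sqrt{\chi^2_2(0.95)\,\lambda_i}$ (the 5.991 quantile), area
$\pi a_1 a_2$.  Each anatomical axis reports the full length of, and the
angle in degrees to, the eigenvector nearest it.  The $\chi^2$ scaling is
the large-sample coverage ellipse; the F-statistic prediction-ellipse
variant differs by $O(1/n)$ and is selectable (`ellipse_method`).  Angles
are reported in degrees — the registry's published unit for the angle rows
(m/s²) is treated as a typo.

## Timed Up and Go

Phases are segmented on discrete-wavelet approximations with the Daubechies
db5 wavelet: level 5 of pitch for sit-to-stand (STS) and stand-to-sit
(StS), level 2 of yaw for the two turns.  The approximation is computed
with a maximal-overlap (undecimated) transform reconstructed from the
level-J approximation coefficients only, mirror-extending the series first;
this keeps the output the same length as the input, zero-phase, and free of
wrap-around artifacts.  The passband is roughly below $f_s/2^{J+1}$
(≈ 0.49 Hz at level 5, ≈ 3.9 Hz at level 2 for 31.25 Hz), so the
approximations isolate the slow postural transitions from cadence-rate
content.

Turns are the two longest intervals where the yaw approximation magnitude
exceeds 15% of its maximum (`tug_turn_frac`), ordered by time, with
landmark *ii* at each interval's magnitude maximum.  STS is the interval
around the largest pitch-approximation extremum before turn 1, StS around
the largest after turn 2; within each, landmark *ii* is the extremum and
*i*/*iii* are the flanking crossings of 10% of the extremum amplitude
(`tug_amp_frac`).  These stage definitions — *i–ii* the first half of the
movement, *ii–iii* the second, split at the angular-velocity extremum — are
one concrete operationalization of "first/second stage" and are
configurable.  A pitch extremum below 10 deg/s (`tug_min_pitch_peak`) is a
segmentation error, not a phase.  Walking phases are the gaps STS→turn 1
and turn 1→turn 2.

Per-phase features are stage-windowed statistics: ranges, means, medians,
standard deviations and maxima of pitch velocity over the stated stages;
mean angular acceleration across a stage as
$\Delta\text{velocity}/\Delta t$; AP-acceleration statistics over *i–iii*;
durations $t_{iii} - t_i$.  Turn features use the yaw *magnitude*, making
them invariant to the turning direction; pitch features are signed (a
stand-to-sit lean is a different movement from a sit-to-stand lean).  Walk
features pool both walking bouts: RMS of the three filtered accelerations,
step-time mean and SD, step count, and total duration.  Turn step counts
take ICs strictly inside the turn interval.  The registry carries all 43
TUG features; `strict_registry` exists as a flag for the variant that drops
the walk duration.

## Synthetic data

The generators exist so that every algorithm is testable against exact
ground truth without any recorded data.  They are seed-deterministic, and
signal and truth are consistent by construction.

`gen_walk()` scripts the vertical CoM displacement as a small Fourier
series: one cosine per step of peak-to-trough excursion `h_amp`, plus two
sidebands implementing side asymmetry — the per-step troughs scale as
$(1 \pm asym)$ on alternating steps while the shared maxima (the contacts)
stay fixed.  The emitted acceleration is the analytic second derivative
with each frequency component multiplied by
$(\tan(\omega/2f_s)/(\omega/2f_s))^2$, the inverse squared gain of the
trapezoid-rule integrator, so that *discrete* double integration at the
output rate reproduces the programmed displacement (within 2% RMS in the
window interior; EMD end effects dominate the first and last second).
Contacts sit at the displacement extrema (one per step), end contacts one
double-support offset (0.2 step) later; yaw is a half-cadence sinusoid
phase-locked so side-A contacts see positive yaw; gaus1-shaped heel-strike
transients (0.3 m/s², 40 ms) exercise the detector on a realistic
morphology; white Gaussian noise (0.1 m/s²) covers every channel; and the
signals are pushed into a tilted sensor frame (2°/1° by default) by the
exact inverse of the anatomical transform.  The walking envelope ramps up
between a displacement zero crossing and the adjacent maximum (and down
symmetrically), so the taper itself cannot create spurious displacement
minima at the bout boundaries.

`gen_sway()` band-limits white 2-D Gaussian noise (default 0.1–2 Hz, the
physiological sway band) and then whitens and recolours it so the sample
covariance equals the request *exactly*.  `gen_tug()` scripts Gaussian
pitch bursts at sit-to-stand and stand-to-sit (σ = 0.5 s, ≈ 2.1 s
movements, peaks 50/−45 deg/s), yaw bursts at the turns (σ = 0.45 s,
peaks 60/70 deg/s) and embeds two `gen_walk` bouts; truth landmarks are the
analytic threshold crossings of the clean script under the same rules the
detector applies.  `gen_session()` assembles the full battery — three SSV
and three FV walk trials (cadences 1.8/2.0 Hz, programmed speeds
1.3/1.6 m/s, excursions derived from the target speeds through the
pendulum model), five sway conditions with increasing covariance (eyes
closed, tandem and one-leg standing sway more), two TUG trials and a
40-step naturalistic bout.

What the generators do *not* emulate: double-support morphology of real
trunk acceleration (so end-contact placement is only structurally, not
biomechanically, validated), soft-tissue and clothing artifacts, turning
steps inside TUG turns, non-stationary cadence, pathological asymmetry
beyond amplitude scaling, and magnetometer-free heading drift.  Passing
tests on this synthetic battery demonstrates algorithmic correctness —
not clinical validity on recorded patients, which requires a gold-standard
comparison via the agreement module.

## Agreement statistics

`bland_altman()` reports the mean difference and the 1.96 SD limits of
agreement, with the percentage form expressed relative to the grand mean of
the pairwise means (the paired-means basis, not the gold standard alone).
`icc_agreement()` is the two-way random-effects, absolute-agreement,
single-measure intraclass correlation computed from the mean-squares
decomposition, with the conventional classes (excellent > 0.9,
good ≥ 0.75, moderate ≥ 0.5, poor below); absolute agreement deliberately
punishes constant offsets that a Pearson correlation would forgive.
`pearson_rmse()` completes the report.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: flat or too-short windows yield
empty event sets with a warning (not an error); all-zero sway windows
report missing spectral features and zero time features; rank-deficient
sway covariance yields a zero-area ellipse with a warning; a constant
series has Hurst exponent 1 by convention; EMD falling back to polynomial
detrending warns.  Ties in the forced-alternation side assignment resolve
toward the yaw-based majority.  The test-suite problem sizes — 20-step
walks across cadences 1.4–2.2 Hz with ten seeds, 30 s sway windows, 50
randomized TUG trials, 10⁵-sample ellipse checks — were chosen to give the
property checks sharp expectations while keeping the whole suite
interactive (well under a minute).

## Worked example

```{r example}
ses <- gen_session(seed = 1)
ft <- suppressWarnings(
  extract_session(ses$recordings, ses$annotations, ses$meta))
ft
subset(as.data.frame(ft), feature_name == "Mean Velocity" |
         feature_name == "Velocity Difference",
       select = c(condition, feature_name, value))
```

The scripted speeds (1.3 and 1.6 m/s) are recovered to within a few
percent, and the velocity difference row equals the difference of the two
mean-velocity rows exactly, by construction of the table.

## Known limitations

* End-contact times inherit the smoothing of the second differentiation;
  stance and swing durations are therefore less sharply validated than
  step and stride times (which the synthetic battery pins to two samples).
* At 31.25 Hz a ±2-sample tolerance is ±64 ms; very fast cadences
  (> 2.5 Hz) compress gait events toward the sampling resolution, and the
  sampling rate — not the algorithm — becomes the accuracy floor.
* The shipped K constants are cohort-specific by design.
* The tilt model corrects static misalignment only; it does not track
  postural reorientation within a trial.
* The TUG segmenter assumes the canonical phase order; protocols with
  extra turns or pauses will fail segmentation loudly rather than produce
  silently wrong phases.
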