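---
title: "Methods: glove kinematics, calibration and spasticity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glove kinematics, calibration and spasticity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Finger spasticity after stroke — velocity-dependent involuntary muscle
contraction, graded clinically on the modified Ashworth scale (MAS) at the
metacarpophalangeal joints — impairs voluntary hand movement. A sensor glove
with 18 nine-axis IMUs on the hand plus a 19th unit on the upper arm, and an
instrumented soft ball with an air-pressure sensor, records subjects
performing five occupational-therapy tasks: cone stacking (CS), slow and
fast finger flexion-extension (S-FE, F-FE), and slow and fast ball squeezing
(S-BS, F-BS), all sampled at 50 Hz. The analysis question is which of the
many summary statistics computable from these streams separate healthy
subjects from subjects with finger spasticity, and grade the MAS level.

The clinical recordings behind this design are not publicly available, so
the package pairs the full analysis chain with a synthetic session generator
that reproduces the *statistical structure* the chain assumes. Everything
downstream of the generator — calibration, attitude estimation, feature
extraction, screening — is identical to what would run on real recordings.

## Signal model of the generator

Each finger-segment IMU follows a smooth periodic flexion trajectory: the
joint angle over one movement cycle is a raised cosine,
$\theta(t) = \tfrac{A}{2}\,(1 - \cos 2\pi f t)$, repeated for the task's
cycle count (50 for the FE and BS protocols; cone stacking, which has no
prescribed count, is modelled as 20 transport cycles). The raised cosine was
chosen because it is smooth, differentiable and analytically checkable: the
gyro reading is its exact derivative, so the cycle-averaged angular-velocity
magnitude is exactly proportional to the excursion $A$ — a property the test
suite asserts. Per-cycle amplitude jitter (5 % sd, shared across IMUs) and
lognormal between-subject multipliers on excursion and pace (8 % sd) supply
within- and between-subject variability.

Sensor channels follow their physics: the gyro is the analytic angular rate
plus bias and white noise; the accelerometer is gravity rotated into the
sensor frame plus a small tangential term from the segment's angular
acceleration plus noise; the magnetometer is the geomagnetic reference field
(22, 0, −42) µT rotated into the sensor frame, then distorted by per-axis
soft-iron scales and an additive hard-iron bias. The world x axis is aligned
with magnetic north, the same heading convention the attitude filter uses.
Ball-squeezing tasks add a pressure channel: ambient baseline plus one
raised-sine-squared pulse per squeeze cycle (2 kPa default height) plus
noise. Default noise levels (0.02 g, 0.5 deg/s, 0.3 µT, 5 Pa) are typical of
the consumer MEMS parts such gloves use.

Spasticity enters only through the mechanism the clinical picture suggests:
slower, smaller, less smooth voluntary movement. MAS levels 0/1/2 map to
excursion (and squeeze-force) multipliers 1/0.7/0.45, pace multipliers
1/0.85/0.7, and added angular-rate tremor noise of 0/3/6 deg/s. These are
generator assumptions chosen once to give a clearly separated, monotone
group structure — they are not clinical measurements, and nothing in the
analysis chain depends on their particular values. There is no
musculoskeletal or EMG model.

Each session opens with 2 s of the glove stationary on the desk (the
accel/gyro bias window) followed by a figure-8 rotation sweep of 2000 frames
— the magnetometer calibration buffer. The sweep is a Lissajous trajectory
over roll, pitch and yaw with six exact field-alignment poses per IMU
inserted, so every magnetometer axis genuinely attains ±|B|: the min/max
calibration below then recovers the planted hard-iron bias exactly in the
noiseless case, which the acceptance checks exploit.

## Calibration

**Pressure ball.** With ambient pressure $p_a$ read while the sensor needle
is exposed to air, every ball reading is reported as the offset
$p' = p - p_a$. Ball hardness is acceptable while $|p'| \le 0.005\,p_a$;
below −0.5 % the ball is too soft, above +0.5 % too hard. The boundary is
classified as acceptable because the two failure conditions are strict
inequalities.

**Magnetometer.** Hard-iron distortion adds a constant offset; soft-iron
distortion scales the axes. From the warm-up buffer, per axis:
$\alpha = (\max + \min)/2$ (bias), $\sigma = (\max - \min)/2$ (half-range),
$\beta = \bar\sigma / \sigma$ (scale, with $\bar\sigma$ the mean of the
three half-ranges); calibrated readings are
$m' = \beta\,(m - \alpha)$. The construction fixes the common radius at
$\bar\sigma$, so re-fitting calibrated data returns $\alpha = 0$,
$\beta = 1$ — an idempotence property the tests assert. Extremes are taken
on the raw samples, exactly as the formulas state; an outlier-sensitive
choice, but the one that matches the printed procedure. Degenerate axes
(max = min) are refused by name rather than producing infinite scales.
Buffers shorter than 2000 samples are allowed with a warning, for
desk-scale testing.

**Accelerometer/gyroscope.** Bias-only: per-axis means over the stationary
window give the gyro bias and the gravity reference, the latter rejected if
its norm strays more than 10 % from 1 g. No scale or orthogonality
correction is attempted — the acquisition procedure (glove at rest on the
desk) identifies nothing more. Stationarity, where it must be detected, is
gyro magnitude below 1 deg/s.

## Attitude and joint angles

No specific fusion algorithm is mandated by the glove's processing contract,
only its inputs (calibrated 9-axis data) and outputs (attitude quaternions,
Euler angles, joint angles). A gain-tunable complementary filter was chosen
over an optimisation-based estimator because it is deterministic, has two
interpretable parameters, and meets the accuracy contracts: gyro
propagation via the quaternion exponential, plus bounded error feedback
from the measured gravity and magnetic-field directions (cross products
against the directions the current attitude predicts, with gains `k_acc`
and `k_mag` in rad/s per unit error; defaults 1 and 0.5). Zero-norm
accelerometer or magnetometer readings skip their correction for that step
and flag the output. Euler angles use the intrinsic Z-Y-X (yaw-pitch-roll)
convention, with a gimbal-lock flag within 0.5° of ±90° pitch. The joint
angle between adjacent sensors is the scalar angle of the relative rotation,
$2\arccos|w_{rel}| \in [0°, 180°]$ — no anatomical flexion/abduction
decomposition is attempted.

The IMU index map (0 = hand dorsum mainboard, 1–15 = finger segments
proximal-to-distal thumb-to-little, 16–17 = palm, 18 = upper arm, elbow =
pair (0, 18)) is a documented convention of this package: feature names such
as `GyroXYZ_9_SD` need stable indices, but the exact placement of every
glove unit is not fully specified by the hardware description.

Screening features are computed from signal magnitudes only (next section);
fused angles serve the clinician-facing view, as stage
`analysis/03_fuse.R` demonstrates.

## Features

Hand movement is three-dimensional, so each sensor triad is reduced to its
per-frame Euclidean norm, giving 57 magnitude channels (19 IMUs × 3
sensors); ball-squeezing tasks add the pressure-offset channel. Each channel
yields 20 statistics on the task segment only (stationary and warm-up
windows excluded, no sub-windowing):

* time domain (8): mean, median, IQR, SD, CV, RMS, skewness, kurtosis;
* frequency domain (12): the first six main frequencies and their
  amplitudes.

That gives the identities the whole design hangs on: 57 × 20 = 1140
features for CS/S-FE/F-FE and 58 × 20 = 1160 for the BS tasks.

Estimator conventions, fixed and documented because the statistic names
alone do not pin them down: quartiles by linear interpolation (type 7), SD
with the n−1 denominator, CV = SD/mean, skewness $g_1 = m_3/m_2^{3/2}$ and
excess kurtosis $g_2 = m_4/m_2^2 - 3$ (moment estimators). Zero-variance
series get skewness = kurtosis = 0 by convention. The CV of a channel whose
mean is numerically zero relative to its scale (possible for the signed
pressure offset) is reported as missing and skipped by screening.

"Main frequencies" are interpreted as the six largest-amplitude local
maxima of the single-sided amplitude spectrum (mean removed, rectangular
window, DC bin excluded), ordered by descending amplitude, with zeros
filling any unused slots. Ranking by amplitude is what "main" most naturally
means; DC is excluded because mean level is already a time-domain feature.

## Screening

Two-level labels pool stroke subjects without spasticity (MAS 0) into the
healthy group — spasticity, not stroke history, is the screened condition.
The two-group test is the unpaired Wilcoxon rank-sum (Mann–Whitney) test:
the groups are independent samples of unequal size (nine vs five), so the
paired signed-rank variant is not applicable to this design. The p-value is
exact by full enumeration of all group assignments (mid-ranks for ties) up
to combined n = 20 — at the cohort's n = 14 that is 2002 assignments, and
the enumerated null distribution is cached per tie pattern — switching to
the tie-corrected normal approximation above. The two-sided p-value is the
null probability of a rank sum at least as far from its expectation as
observed.

Features are significant at p < 0.05 with **no multiple-testing
correction**: the screening is deliberately per-feature descriptive, and the
robustness device is instead the *all-IMUs* aggregation — a (sensor,
statistic) pair is reported only when significant for every one of the 19
IMUs, which under the null has essentially zero probability
($\approx 0.04^{19}$). A Benjamini–Hochberg option exists but is off by
default. The most significant kinematic feature per task (and pressure-ball
feature for BS tasks) is selected by smallest p-value with a deterministic
lexicographic tie-break — ties are guaranteed at this sample size, where the
smallest attainable two-sided p is $2/\binom{14}{9} \approx 0.001$.
Selection considers all features by default (an option restricts candidates
to all-IMU-significant pairs, a stricter reading that the design leaves
open). Selected features are then graded across MAS 0/1/2 with the
Kruskal–Wallis test (tie-corrected H, chi-square reference; an exact
enumeration option exists for total n ≤ 14 and is verified against an
independent enumeration in the tests).

One statistical caveat the tests quantify rather than hide: the exact
two-sided test at group sizes (9, 5) is discrete, so its attainable level at
the 0.05 cutoff is 0.042, not 0.050. The type-I property test therefore
compares the empirical rate under label permutation against the attainable
level computed at run time from the enumerated null distribution.

## What the generator does and does not establish

Passing tests on synthetic cohorts show that the chain — calibration,
fusion, feature extraction, exact tests, selection logic — is correct and
that the screening detects a planted velocity effect with the qualitative
pattern expected (angular-velocity centrality features significant for every
IMU, magnetometer shape features not). They do **not** show that real
spastic movement produces that effect size, nor reproduce any clinical
cohort's p-values: the generator's effect sizes are assumptions, real
tremor is not white noise, real magnetometer distortion is not purely
hard/soft iron, and real task execution has pauses and compensatory
movements the raised-cosine model lacks.

## Numerical choices and problem sizes

Quaternions are renormalised after every update and the Euler round-trip is
exact to well below 1e−6° away from gimbal lock. Enumeration comparisons
use a 1e−9 slack on rank-sum extremeness to keep ties stable in floating
point. The packet codec uses dyadic fixed-point steps (1/2048 g, 1/16
deg/s, 1/4 µT, 1/64 Pa) so quantisation is exact in binary floating point
and round-trips are bit-identical on the grid.

The shipped analysis scripts and acceptance checks run the full study
conditions — 14 subjects, 50-cycle tasks, 2000-frame warm-up, 200 label
permutations for the type-I rate. Unit tests exercise the same code on
shorter sessions (2–5 cycles, 300-frame warm-up, which still covers the 114
inserted alignment poses) purely to keep the logic checks fast; no
statistical claim rests on the reduced sizes.

## Known limitations

* Min/max magnetometer calibration handles diagonal soft-iron only; a
  rotated soft-iron ellipsoid would need an ellipsoid fit, deliberately out
  of scope.
* The complementary filter trusts the accelerometer as a gravity reference;
  during vigorous movement the motion term biases it, and heading is only
  weakly observed — the joint-angle demo therefore measures cycle
  amplitudes spectrally rather than as raw excursion ranges.
* Screening at n = 14 has limited power and heavily tied minimal p-values;
  the selection tie-break is deterministic but arbitrary among tied
  features.
* The generator's spasticity model is kinematic only; no claim of
  biomechanical realism is made.
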