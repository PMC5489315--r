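---
title: "Methods: inertial tuning analysis of cerebellar-style unit activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertial tuning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Freely moving animals generate rich three-dimensional head movements. A
head-mounted inertial measurement unit (IMU) senses exactly what the
vestibular organs sense: angular velocity $\Omega$ about the three
head-bound axes (gyroscope, like the semicircular canals) and total
acceleration $A$ (accelerometer, like the otoliths), which conflates
gravity with inertial acceleration. The analyses in this package ask, for
simultaneously recorded single units, *which functions of these inertial
signals drive the firing rate* — and in particular whether a unit's
rotational tuning is anchored to the head or to gravity.

The package implements the full chain: gravity decomposition of the IMU
signals, a model-free resampling estimator of movement-driven firing rate,
lag-resolved 3D rotational sensitivity vectors, spherical tilt receptive
fields, tilt-stability and reference-frame classification, and linear-model
baselines — together with a synthetic-data generator that plants known
tuning models so every stage is testable without recordings.

# Conventions

* Head frame: $x$ naso-occipital (forward), $y$ interaural (leftward), $z$
  dorsal, right-handed. An upward (nose-up) pitch is a **negative**
  $\omega_y$; a leftward yaw is a positive $\omega_z$. Nose-up tilt gives
  $a^G_x > 0$.
* Quaternions are scalar-first $(w, x, y, z)$ and map sensor-frame vectors
  into the earth frame, $v_E = q\,v_S\,q^*$. The gravity direction in head
  coordinates is the converse rotation of earth-up, $a^G = q^*\,e_z\,q$.
* Angular velocity is stored in deg/s everywhere and converted to rad/s
  only inside physics formulas. Accelerations are in units of $g$.
* Upright at rest reads $a^G = (0, 0, +1)\,g$ (the accelerometer measures
  the support reaction, not gravity itself).

# Orientation filter and gravity decomposition

`estimate_orientation()` is a quaternion complementary filter: each step
propagates the orientation by the exact quaternion exponential of the
(trapezoid-midpoint) gyro increment, then rotates the estimate so that the
predicted gravity direction moves toward the normalized accelerometer
vector by a fraction `correction_gain` of the angle between them (a SLERP
step). The published analysis used an established gradient-descent IMU
filter whose internal constants are not restated in the text we implement
from; the complementary form has one interpretable parameter, identical
steady-state behavior, and exact testable endpoints: gain 0 is pure gyro
integration, gain 1 snaps the gravity estimate to the accelerometer. The
default gain of 0.01 per sample at 250 Hz corresponds to a tilt correction
time constant of about 0.4 s — slow enough that rotation-induced
(non-gravitational) accelerations barely perturb the tilt estimate, fast
enough to absorb gyro noise; on noiseless synthetic sessions the median
gravity-direction error is ~0.3°, and < 3° with default sensor noise.

Heading is gyro-integrated (there is no magnetometer in this setting), so
absolute azimuth is unobservable and drifts with gyro noise. With the
synthetic noise defaults the drift over a 600-s session is well under a
degree, which is why earth-frame ("external") re-expression of angular
velocity via the full quaternion is valid here; on real hardware with gyro
bias this choice would need revisiting (a tilt-only alternative would drop
the heading-dependent components).

The decomposition is exact by construction: $A^G$ is the unit-norm
converse-rotated earth-vertical (scaled to 1 g), and $A^{nG} = A - A^G$,
so `acc = ag + ang` holds to machine precision on every sample.

# The synthetic world

`simulate_head_kinematics()` emulates the published kinematic statistics of
rat exploratory head movement; no generative model of rat head kinematics
has been published for this setting, so the generator emulates reported
summary statistics rather than reproducing any particular recording:

* **Fast rotations**: sums of band-limited Gaussian noise (defaults 1–4,
  4–10, 10–20 Hz with decreasing weights), giving multi-peaked spectra up
  to 20 Hz. A lognormal envelope (OU exponent, 0.8 s correlation) makes
  movement bursty, which fattens the speed tail realistically. Roll is
  attenuated (default 0.5) to reproduce pitch/yaw dominance.
* **Slow tilt**: an OU angular-velocity component (correlation time
  `tilt_correlation_time`, default 2 s) plus a gravity-restoring feedback
  (`restore_gain`, default 0.35 s⁻¹) that keeps the head loosely upright,
  as a behaving animal does. The resulting tilt trajectory is
  autocorrelated over seconds, covers median tilts of ~30° with excursions
  past 90°, and concentrates $A^G$ power below 2 Hz (≈99% of acceleration
  power below 2 Hz is gravitational, matching the published regime).
* **Speed percentiles**: with the default `rotation_scale = 55` deg/s the
  2.5–97.5 angular-speed percentiles (computed over samples faster than
  15 deg/s, as in the source analysis) land near 19–270 deg/s, inside the
  published 18–287 deg/s envelope. These defaults were calibrated once to
  those stated targets and then frozen.
* **Accelerometer**: gravity reaction plus lever-arm terms
  $\dot\omega \times r$ and $\omega \times (\omega \times r)$ for a sensor
  ~2 cm from the rotation pivot (default $r = (-2, 0, -2)$ cm), plus white
  noise (defaults: 0.01 g accelerometer, 0.5 deg/s gyro).

The ground-truth orientation is *defined* as the exact quaternion
integration of the emitted angular-velocity series, so orientation-filter
accuracy is measurable without ambiguity.

**Spiking.** `simulate_unit()` evaluates a planted rate model — linear in
head- or earth-frame angular velocity at a response lag, a von
Mises–Fisher bump of the gravity direction for tilt units, or a
tilt-gated/sign-reversing rotational term — rectifies at zero, and draws
spikes by time-rescaling a gamma renewal process with shape $1/\mathrm{CV}^2$.
One knob controls regularity; the rate is matched exactly in expectation.

**What a green test does not establish.** The generator has no sensor
bias or temperature drift, no translation, no behavioral states, and its
renewal spiking has no refractory period. The last point matters
quantitatively: for CV near 1 the reciprocal-ISI rate signal has a
time-weighted second moment of $k/(k-1)$ times the squared rate
($k = 1/\mathrm{CV}^2$), i.e. an order of magnitude of "noise" variance
that real, refractory neurons do not show. Estimator predictability
($R^2$) on synthetic CV-0.95 units is therefore intrinsically much lower
than the values the source study reports for real units of comparable CV.
Parameter-recovery tests consequently use planted units at the regular end
of the observed range (ISI CV 0.45–0.6, gains 0.35–0.45 deg⁻¹; the
strongly rotation-selective units in the source data include
regular-firing mossy fibers, and its mean rotation-selective gain is
0.28 ± 0.15 deg⁻¹), while the recovery test of the tuning *parameters*
keeps the conventional values (gain 0.2 deg⁻¹, lag 40 ms, CV 0.95), which
OLS recovers regardless of rate noise.

# The model-free resampling estimator

`estimate_rate()` predicts the instantaneous firing rate at time $i$ as
the mean of $\mathrm{FR}^{instant}$ observed at reference samples $j$ whose
inertial parameters lie within a distance $d$ of the query's, excluding
temporal neighbors ($|t_j - t_i| \le w$, default 1 s, applied when query
and reference are the same recording). Implementation choices:

* **Metric**: Euclidean distance on per-channel z-scored coordinates,
  scales taken from the reference set, so $d$ is comparable across
  parameter sets of different dimension.
* **Radius**: by default $d$ is tuned per recording and channel set so the
  median neighbor count is 200 (probe-subsample k-th-nearest-neighbor
  distance); samples with fewer than 10 covered neighbors are undefined
  and excluded pairwise from correlations.
* **Search**: an exact k-d tree (Rcpp); a brute-force all-pairs oracle in
  the test suite reproduces the estimator on 5,000-sample inputs to
  1e-12 (differences only from floating-point summation order).
* **Lags**: the neighbor sets depend only on the parameters, so a lag scan
  re-uses them, pairing the estimate with the rate series shifted by the
  lag; positive lag means firing follows movement. Default grid
  −500…+500 ms in 20 ms steps.
* **Predictability** $R^2$ is the squared Pearson correlation between the
  estimate and $\mathrm{FR}^{instant}$ on covered samples; per-set values
  are reported at the per-set best lag. On long recordings the query side
  may be strided (`query_stride`) — the reference set stays complete —
  which changes $R^2$ only by sampling noise.
* **Robustness**: independent estimates from alternating 30-s blocks, and
  a null from circularly shifted spike trains (offset ≥ 10 s, preserving
  ISI structure).

Coverage interacts with tuning strength: the undefined samples are exactly
the extreme-parameter excursions, which carry a disproportionate share of a
tuned unit's rate variance, so reported $R^2$ is conservative for strongly
driven units.

# Rotational sensitivity and receptive fields

`fit_sensitivity_at_lag()` is the OLS fit
$\mathrm{FR}(t + \mathrm{lag}) = c + \lambda \cdot \omega(t)$; the
coefficient vector $\lambda$ is the sensitivity vector, its norm the gain
(Hz per deg/s, equivalently deg⁻¹), its direction the preferred rotation
axis. `gain_lag_curve()` scans lags and flags significance when the peak
gain exceeds the mean + 2 SD of gains from circularly time-shifted rate
series (100 shifts; a single shift alignment represents every lag because
the shift distribution is uniform). The noiseless gain-vs-lag curve of a
planted unit is unimodal near the true lag; side lobes further out
reflect the oscillatory autocorrelation of $\omega$ itself.

`inertio_temporal_rf()` bins one kinematic channel (20 bins spanning the
1st–99th percentile; cells under 50 samples masked) against the lag grid,
optionally conditioned on a gravity predicate; a dead zone
$|a^G_{axis}| \le 0.1$ g is excluded from both hemifields in conditioned
analyses to avoid boundary dilution.

# Tilt maps, stability, and reference frames

`tilt_rate_map()` averages the rate over samples whose gravity direction
falls within 20° caps centered on a 642-point Fibonacci lattice
("evenly distributed points" is under-specified in the source; the
Fibonacci lattice is deterministic and quasi-uniform). Overlapping caps
smooth the map; the map CV (SD/mean over occupied points, ≥ 500 samples
each) quantifies tilt dependence of the rate. `lambert_project()` is the
standard equal-area azimuthal projection (planar radius $2\sin(\theta/2)$).

`stability_index()` fits sensitivity vectors separately for the two
hemifields of one gravity component ($a^G_{axis} > 0.25$ g vs
$< -0.25$ g) across a lag range and returns the gain-weighted mean cosine
between the hemifield vectors (weights: the smaller of the two gains per
lag, because direction is meaningless where either gain vanishes; the
source's exact weighting is not published, so this definition is declared
rather than inherited). +1 means tilt-independent tuning; −1 a reversal.

`local_sensitivity_field()` fits, per 20° tilt cap with ≥ 500 samples,
sensitivity vectors against head-frame and against earth-frame angular
velocity. Per-cap significance uses the same circular-shift band (50
shifts); insignificant vectors are excluded from collinearity profiles
because noise vectors have random directions and bias collinearity toward
zero. `collinearity_profile()` averages, in 10° bins of tilt separation
$\varphi$, the dot products of normalized vector pairs;
`classify_reference_frame()` takes
$\Delta S = \overline{S_{ext} - S_{int}}$ over $\varphi \in [80°, 100°]$
and labels a unit external if $\Delta S > 0.5$, internal if $< -0.5$ —
the cutoff printed in the source study.

A geometric caveat the tests respect: a head-frame unit tuned to *yaw* is
nearly indistinguishable from an earth-vertical unit at small tilts, so
frame-recovery tests use a pitch-tuned head-frame exemplar and an
earth-vertical external exemplar.

# Linear-model baselines

`global_linear_fit()` regresses the rate on combinations of $\omega$,
$\dot\omega$, $a^G$ and $\dot a^G$ over the whole recording (in-sample
$r^2$, matching the descriptive use in the source).
`local_linear_r2()` assigns each sample to its nearest occupied tilt cap
(disjoint partition within the cap radius), refits the rotational model
per cell, and pools the coefficient of determination across assigned
samples (pooling residuals, rather than averaging per-cell $r^2$, weights
cells by occupancy; the source's choice is not published).

One subtlety: a gate of the form $\mathrm{sign}(a^G_x)\,\omega_z$ is
*partially* inside the span of the gravity-jerk regressor, because
$\dot a^G_y$ contains the product $g_x\,\omega_z$. That is genuine
physics, not leakage. The model-hierarchy tests therefore use a gated unit
whose tuning axis equals its gate axis ($\mathrm{sign}(a^G_y)\,\omega_y$),
which no linear combination of the four regressor blocks can express —
reproducing the published qualitative structure (model-free ≫ global
linear; tilt-local linear ≈ model-free).

# Numerical and degenerate-input policy

* Decomposition identities hold to machine precision; unit-norm
  invariants to 1e-9.
* Derivatives: central differences in the interior, one-sided at the
  ends; no smoothing (callers can smooth).
* Rank-deficient OLS designs are flagged (`ok = FALSE`) or, for global
  fits, solved minimum-norm with a warning.
* Zero-variance targets define $r^2 = 0$ rather than NaN.
* Exactly-at-threshold values pass upward: entropy exactly 6.3 bits is
  *not* a mossy fiber; $\Delta S$ exactly ±0.5 is unclassified.
* Fewer than 2 spikes: a zero rate series with a warning; empty tilt caps
  and φ bins are masked, never interpolated.
* Seeds: every stochastic routine takes an explicit seed; sessions,
  fixtures and pipeline outputs are bit-reproducible under a fixed seed.

# Known limitations

* No magnetometer, bias, or calibration modeling; heading validity rests
  on the generator's drift-free gyros.
* The entropy estimator (log₂-ISI histogram, 0.02-bit bins over 1 ms–10 s)
  follows the spirit of the cited classification scheme; the 6.3-bit
  cutoff may not transfer exactly to other estimators, so the synthetic
  calibration (Poisson ≈ 8.1 bits, CV 0.42 ≈ 7.0, highly regular ≈ 5.5)
  is documented rather than assumed.
* Population-level statistics of the source study (86 real units) are not
  reproducible from synthetic data and are not claimed; acceptance is
  property- and recovery-based.
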