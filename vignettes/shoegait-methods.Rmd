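---
title: "Methods: shoe-sensor gait analysis in shoegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shoe-sensor gait analysis in shoegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoegait)
```

## The measurement problem

An instrumented shoe carries four triaxial force sensors under the heel,
first metatarsal head, fifth metatarsal head and toe (sampled at ~400 Hz),
plus one inertial measurement unit (IMU) glued to the shoe tip ~0.03 m above
the ground (sampled at ~70 Hz, emitting calibrated-or-raw accelerations and
orientation quaternions from its fusion engine). From these two streams the
package estimates, per walking trial:

* **localized ground reaction forces (GRF)** — each sensor's force triplet
  rotated from the tilting shoe frame into a ground-fixed frame, segmented
  into stance phases and time-normalized to 101 samples (0 % = heel contact,
  100 % = toe off);
* **stride length** — double integration of the globally framed toe
  acceleration between successive flat-foot phases, with zero-velocity
  updates (ZUPT);
* **toe clearance and its mid-swing minimum (MTC)** — the vertical IMU
  travel plus the mounting height; small, variable MTC is the canonical
  trip-risk marker in older adults;
* **group statistics** — per-participant means and coefficients of
  variation (CV), height/body-mass normalization, pooled-variance t tests,
  Cohen's d, and Bland–Altman agreement against a reference.

Because no raw recordings are deposited anywhere, the package ships a
synthetic gait generator that emits both sensor streams plus the underlying
truth, so every processing stage is verifiable at desk scale.

## Processing pipeline

### Accelerometer calibration

Stationary readings taken in ≥ 6 varied postures constrain a six-parameter
model (per-axis gain and bias, no cross-axis terms): the calibrated norm
must equal 9.81 m/s² in every posture. `fit_calibration()` minimizes
the sum of squared norm residuals by damped Gauss–Newton iteration from
gain (1,1,1), bias (0,0,0), stopping when the parameter step norm falls
below `1e-10` (max 100 iterations). The damping (Levenberg-style, rejected
steps inflate the damping parameter tenfold) makes the accepted objective
sequence non-increasing, which the tests assert. Twenty postures — the
configuration the hardware procedure uses — recover synthetic gains/biases
to `1e-6` without noise and keep the mean calibrated norm within
±0.02 m/s² at 0.02 m/s² posture noise.

### Initial attitude: a deliberate convention choice

Two initializers are exported. `initial_angles()` evaluates the literal
textbook formulas `theta0 = -atan2(a_z0, a_x0)`,
`phi0 = arctan(a_x0 / sqrt(a_y0² + a_z0²))`, `psi0 = 0`. One can show,
however, that **no** stationary reading makes the z–y–x global rotation
`Rz(psi) Ry(phi) Rx(theta)` built from these angles map the reading onto
`(0, 0, 9.81)`: for a level foot (gravity along z′) they yield
theta0 = −90°, which would swap the vertical and forward axes and leak the
full gravity vector into the horizontal channels. The formulas evidently
presuppose an IMU mounting convention that the rest of the algorithm does
not share.

The pipeline therefore uses `initial_angles_gravity()`:
`theta0 = atan2(a_y0, a_z0)`, `phi0 = -atan2(a_x0, sqrt(a_y0² + a_z0²))`,
the unique z–y–x attitude (with psi0 = 0) under which gravity subtraction
cancels exactly at rest. This is the only initialization compatible with
the downstream gravity-removal step; the literal variant remains available
for data recorded under the alternative mounting.

### Euler-angle accumulation

During walking, consecutive quaternions `q_{k-1}, q_k` give a relative
rotation `q_k ⊗ q_{k-1}⁻¹`, which is decomposed into intrinsic z–y–x Euler
increments and summed onto the running angles. Two properties matter:

* quaternion measurement noise *telescopes* — the accumulated error stays
  at the single-sample noise level instead of random-walking;
* the summed increments equal the integrated angular velocity. For planar
  rotation (foot pitch, the dominant motion in straight-line gait) this is
  *exactly* the Euler angle at any sample rate; for genuinely three-axis
  motion the sum tracks the Euler trajectory to second order in the
  excursion amplitude. The tests pin both regimes.

A gimbal guard clamps the decomposition near |phi| = 90°, where the z–y–x
parameterization is singular; straight-line gait stays far from it.

### Frame transforms

Localized forces use `R = Ry(phi) Rx(theta)` (heading-free: a force's
vertical and horizontal components do not depend on walking direction);
IMU accelerations use `R = Rz(psi) Ry(phi) Rx(theta)`. Orientation angles
live on the 70 Hz IMU clock and are linearly interpolated onto the 400 Hz
force clock; kinematics runs entirely on the IMU clock. Both matrices are
orthonormal by construction and preserve force magnitudes to `1e-9`, which
the property tests check against per-sample matrix-product oracles.

### Filtering

* Force channels: fourth-order Butterworth low-pass, 50 Hz cutoff, applied
  forward–backward (zero phase) so stance-event timing is not lagged.
  Offline analysis makes zero-phase filtering free; it squares the
  magnitude response, and the filter tests compare measured sine gains
  against the prewarped digital Butterworth magnitude.
* Channel offsets are removed by subtracting the per-channel median over
  unloaded (swing) samples, identified by a preliminary stance detection.
* IMU accelerations: `bandpass_accel()` implements the 1.0 Hz to
  `min(40, 0.45·fs)` Hz band-pass as a cascade of fourth-order high- and
  low-pass sections (an 8-pole direct band-pass at a normalized corner of
  0.029 is numerically fragile); the upper corner is clipped below the
  Nyquist frequency of the 70 Hz IMU clock, which a literal 40 Hz corner
  would exceed.

**Where the band-pass is used is a deliberate design decision.** The
high-pass corner (1.0 Hz) sits *above* the stride fundamental of normal
walking (~0.9 Hz at 0.9 strides/s). Since displacement is dominated by the
fundamental after the 1/ω² weighting of double integration, high-passing
the acceleration before integrating removes most of the real stride
displacement: on simulated gait the stride-length RMSE degrades from
~0.005 m to ~0.95 m. The pipeline therefore feeds the integrator the
*low-passed* global acceleration only, and delegates low-frequency error
control to the per-stride ZUPT drift cancellation, which is the mechanism
actually suited to it. The full band-pass remains available and is the
documented default of `to_global_accel()` for uses that do not integrate.

### Flat-foot detection and stride segmentation

A sample is flat-foot when the raw acceleration norm lies within
9.81 ± 0.8 m/s² *and* the gravity-removed global acceleration norm is
below 1.0 m/s², sustained ≥ 0.05 s. The dynamic-norm condition is evaluated
on the *unfiltered* gravity-removed signal: zero-phase high-passing smears
the ±35 m/s² swing bursts several tenths of a second into the quiet flat
windows (residuals of 6–8 m/s²), which would mask every flat phase. The
thresholds are configurable; their defaults were chosen once from the
simulator's noise floor (~0.1 m/s² at rest) and typical swing magnitudes,
with two orders of magnitude of separation.

One stride spans the midpoints of consecutive flat-foot runs, so
integration drift cannot accumulate across strides. The swing start is the
end of the stride's opening flat-foot run.

### ZUPT integration and drift cancellation

Per stride and axis, acceleration is integrated by the trapezoidal rule
from zero initial velocity. The residual end-of-stride velocity — zero in
truth, nonzero through noise, residual bias and filter leakage — is modeled
as linearly accumulated drift and removed by subtracting the ramp
`v_err · (t − t0)/(t1 − t0)`; the corrected velocity integrates to
position, and the vertical position is additionally pinned to zero
displacement at stride end (the foot returns to ground level). The
correction is applied to all three axes; a constant acceleration bias is
annihilated *exactly* (the tests assert end velocity and end vertical
displacement at `1e-12`). Stride length is the Euclidean norm of the
horizontal displacement; clearance is `z(t)` plus the 0.03 m mounting
height, deliberately not clamped at zero so integration faults stay
visible. MTC is the lowest interior local minimum of the clearance inside
the central 25–75 % of the swing (the window operationalizes "mid-swing"),
falling back to the window minimum for monotone traces.

At 70 Hz the dominant kinematic error is trapezoid discretization of the
fast vertical path: single strides with large clearance amplitudes can err
by ~9 mm in MTC while the RMSE over many strides stays near 3 mm.

### Statistics

CVs use the sample (n−1) standard deviation over mean. Group comparisons
are Student's pooled-variance t tests (Welch available via a flag) on
participant-level values, with pooled-SD Cohen's d. Stride length and MTC
are normalized by participant height, GRFs by body mass — the cohort
statistics make this assignment unambiguous even though the source text
once says "kinetic" where it reports kinematic parameters. Agreement
reports give Pearson r, RMSE, bias and Bland–Altman limits
`bias ± 1.96·sd(differences)`.

## The synthetic gait generator

`simulate_session()` emits a 1 s stationary lead-in, `n` strides (swing
then flat-foot stance at cadence 0.9 strides/s, stance fraction 0.60,
both fixed — timing variability is not needed by any estimand here), and a
1 s lead-out, on asynchronous 400 Hz force and 70 Hz IMU clocks to
exercise the synchronization path.

* **Toe path.** Horizontal displacement follows a minimum-jerk profile
  reaching the commanded stride length; the clearance curve is a C²
  piecewise minimum-jerk path through (h0, 3·MTC, MTC, 2·MTC, h0) at
  0/25/50/75/100 % of swing, so the mid-swing dip equals the commanded MTC
  exactly and is a strict local minimum. The curve is built directly in
  *clearance* (IMU height above ground): the dip may legitimately lie
  below the 0.03 m standing height — older adults' MTC (~0.018 m) does —
  which a curve built in displacement with a dip equal to MTC could not
  represent. World acceleration is the analytic second derivative, so the
  emitted IMU stream is exact to the noise model.
* **Profiles.** Young: normalized stride 0.670 (CV 0.0534), normalized MTC
  0.0196 (CV 0.30), heel-first contact; older: 0.655 (CV 0.0858), 0.0120
  (CV 0.71), flat contact; anthropometrics per cohort. Per-stride stride
  lengths are Normal; per-stride MTC is **lognormal** with the requested
  mean and CV. A Normal truncated at 0.001 m — the obvious alternative —
  cuts ~8 % of the older cohort's left tail and deflates its realized CV
  from 0.71 to ~0.53, so no pipeline could recover the nominal value from
  such data; the lognormal has positive support, keeps mean and CV exact,
  and matches the right skew of real MTC distributions.
* **Sensors.** The IMU stream applies the inverse calibration (divide by
  gain, add bias: defaults 1.02/0.98/1.01 and 0.10/−0.05/0.08 m/s²),
  white noise (0.05 m/s²) and quaternion angle noise (0.2°); each session
  also carries 20 stationary calibration postures (0.02 m/s² noise)
  generated under the same gain/bias so the pipeline must actually
  calibrate. Forces follow a double-bump vertical template (1.1 body-weight
  peaks, 0.85 valley, stance impulse ≈ 0.87·BW·duration), a biphasic
  braking/propulsion forward component and a small lateral one,
  distributed over the four sensors with style-dependent weights
  (heel-first loads the heel early; flat contact shifts early load toward
  toe and metatarsals), rotated into the sensor frame and perturbed with
  1 N noise.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: foot pitch during stance (stance is fully
stationary), turning or non-straight paths, soft-tissue and shoe-sole
compliance, sensor saturation, slippage between IMU and shoe, non-white
sensor noise, and localized-GRF waveforms beyond their qualitative
early/mid/late loading pattern (no quantitative contribution data exist to
calibrate against). Recovery bounds met on this generator demonstrate the
*algorithm's* correctness, not field accuracy of the hardware.

## Problem sizes and runtime

The default verification sizes are 12 sessions × 10 strides (young,
default noise) for the per-stride recovery bounds and 20 replicate cohorts
of 15 older participants × 10 strides for the group-structure checks —
about 3 000 analyzed strides in roughly half a minute on one core. Typical
results: stride-length RMSE ~0.004 m and MTC RMSE ~0.004 m against truth
(the hardware-validation figures these are bounded by are 0.10 m and
0.0056 m); the older cohort's mean per-participant MTC CV comes out
~0.63–0.66 against the generative 0.71, the gap being the small-sample
bias of a 10-stride sample CV under a heavily skewed distribution — a bias
the original 10-stride protocol shares.

## Known limitations

* Heading (psi) is unobservable from accelerometer + relative quaternions
  alone; straight-line walking keeps it near zero, but long trials with
  yaw drift would need magnetometer or trajectory-level correction.
* The Euler accumulation is exact only for planar rotation; strongly
  three-dimensional foot motion (turning) would need direct quaternion
  propagation.
* The 70 Hz IMU clock limits MTC accuracy through trapezoid
  discretization; doubling the rate roughly quarters that error
  (the convergence test covers 70/140/280 Hz).
* Contribution percentages for the shear directions use signed segment
  means and are reported as `NA` where the total's segment mean is within
  1 N of zero, since signed shear totals legitimately cross zero.
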