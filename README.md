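# shoegait

Gait analysis for an instrumented shoe that combines four plantar triaxial
force sensors (heel, first and fifth metatarsal heads, toe; ~400 Hz) with a
toe-mounted IMU (~70 Hz). The package turns the two raw sensor streams into
localized three-directional ground reaction forces (GRF), stride length,
toe clearance and minimum toe clearance (MTC), and the group statistics
used to compare young and older adults' gait. It is aimed at biomechanics
and wearable-sensing researchers who want the full processing chain of such
a shoe system as tested, scriptable code — including a synthetic gait
generator that stands in for the hardware, so the whole pipeline is
verifiable without any recordings.

## What it computes

**Kinetics.** Shoe-local force triplets (F<sub>x′i</sub>, F<sub>y′i</sub>,
F<sub>z′i</sub>) are low-pass filtered (4th-order Butterworth, 50 Hz,
zero-phase), offset-corrected, and rotated into the ground frame per force
sample with R = R<sub>y</sub>(φ)·R<sub>x</sub>(θ) using Euler angles
interpolated from the IMU clock. Stance phases run from ΣF<sub>zi</sub>
rising through 15 N to falling below it, are time-normalized to 101 samples
(0 % heel contact … 100 % toe off), and summarized as body-mass-normalized
totals and per-sensor contribution percentages over ten 10 % segments.

**Kinematics.** Orientation is tracked by summing z–y–x Euler increments of
relative quaternions onto a gravity-consistent initial attitude; local
accelerations are rotated with
R = R<sub>z</sub>(ψ)·R<sub>y</sub>(φ)·R<sub>x</sub>(θ), gravity-subtracted,
and double-integrated per stride between flat-foot midpoints with
zero-velocity updates: the residual end-of-stride velocity is removed as a
piecewise-linear drift ramp and the vertical position is pinned to zero at
stride end. Stride length is the horizontal displacement norm; toe
clearance is z(t) + 0.03 m (IMU mounting height); MTC is the mid-swing
(25–75 %) local minimum.

**Statistics.** Per-participant means and coefficients of variation,
height/body-mass normalization, pooled-variance unpaired t tests with
Cohen's d, and Pearson/RMSE/Bland–Altman agreement reports.

**Simulation.** `simulate_session()` generates ground-truth sessions:
minimum-jerk toe paths with an exact commanded MTC dip, style-dependent
plantar load distributions (heel-first vs flat contact), realistic sensor
gain/bias/noise corruption, calibration posture sets, and per-stride truth
tables. Cohort profiles default to the published young/older statistics
(normalized stride 0.670/0.655, stride CV 0.0534/0.0858, normalized MTC
0.0196/0.0120, MTC CV 0.30/0.71).

## Worked example

Simulate an older-adult session, run the full pipeline, and compare the
estimates with the simulator's truth:

```r
library(shoegait)

ses <- simulate_session(default_profiles()$older, n_strides = 10, seed = 42)
an  <- analyze_session(ses)

head(an$strides[, c("stride_index", "stride_length_m", "mtc_m")], 3)
#>   stride_index stride_length_m  mtc_m
#> 1            1          1.0945 0.0076
#> 2            2          1.1192 0.0119
#> 3            3          1.0933 0.0121

an$participant[, c("mean_stride_length", "cv_stride_length",
                   "mean_mtc", "cv_mtc")]
#>   mean_stride_length cv_stride_length mean_mtc cv_mtc
#> 1               1.13           0.0747   0.0132  0.717

agreement(an$strides$mtc_m, ses$truth$mtc_m)[c("r", "rmse", "bias")]
#> $r [1] 0.991   $rmse [1] 0.0016   $bias [1] -0.0001
```

The stride table lists each stride's length (m) and minimum toe clearance
(m); this participant walks ~1.13 m strides with a low (13 mm), highly
variable (CV 0.72) toe clearance — the older-adult pattern the profile
encodes. The agreement report shows the pipeline recovering the simulated
MTC to 1.6 mm RMSE with negligible bias. `an$segment_summary` and
`an$contributions` hold the body-mass-normalized total GRF (N/kg) and the
per-sensor contribution percentages for each 10 % stance segment.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/shoegait.R simulate --out ses1 --group older --strides 10 --seed 42
Rscript inst/cli/shoegait.R analyze  --session ses1 --out results1
Rscript inst/cli/shoegait.R agreement --session ses1 --out agreement.json
```

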