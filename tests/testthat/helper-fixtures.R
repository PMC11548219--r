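# Shared fixtures built in code.

# quaternion stream synthesized from Euler-angle ramps about a single axis
quat_ramp <- function(axis, angles_deg) {
  t(vapply(angles_deg, function(a)
    shoegait:::quat_from_axis_angle(axis, a * pi / 180), numeric(4L)))
}

# stationary IMU stream: identity orientation, gravity-only readings
stationary_imu <- function(n = 100, fs = 70, g = 9.81) {
  t <- seq(0, by = 1 / fs, length.out = n)
  imu_stream(t, matrix(rep(c(0, 0, g), each = n), ncol = 3L),
             matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4L))
}

# force stream with a single channel carrying a given signal
single_channel_force <- function(time, signal, channel = "fz1") {
  f <- matrix(0, length(time), 12L)
  fs <- force_stream(time, f)
  fs[[channel]] <- signal
  fs
}

# readings generated from a known calibration model: for true gain/bias the
# emitted raw reading is dir * 9.81 / gain + bias
postures_from_model <- function(gain, bias, n = 20, seed = 1, noise_sd = 0) {
  withr::local_seed(seed)
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  raw <- sweep(9.81 * dirs, 2L, gain, "/")
  raw <- sweep(raw, 2L, bias, "+")
  raw + stats::rnorm(length(raw), 0, noise_sd)
}

# analytic magnitude response of the zero-phase digital Butterworth
# (bilinear-transform design, so frequencies are prewarped; filtfilt applies
# the squared magnitude)
butter_mag2 <- function(f, fc, fs, order = 4, type = c("low", "high")) {
  type <- match.arg(type)
  r <- tan(pi * f / fs) / tan(pi * fc / fs)
  if (type == "low") 1 / (1 + r^(2 * order)) else
    r^(2 * order) / (1 + r^(2 * order))
}

# empirical gain of a filter at one frequency, measured as the sd ratio over
# the central part of a long sinusoid (robust to sample-phase granularity)
sine_gain <- function(filter_fun, f_hz, fs, n_cycles = 40) {
  t <- seq(0, n_cycles / f_hz, by = 1 / fs)
  x <- sin(2 * pi * f_hz * t)
  y <- filter_fun(x)
  core <- seq(round(length(y) * 0.3), round(length(y) * 0.7))
  stats::sd(y[core]) / stats::sd(x[core])
}
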