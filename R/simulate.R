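#' Gait profile describing a participant group
#'
#' Bundles the statistical structure of a cohort: height-normalized stride
#' length and minimum toe clearance (mean and CV), cadence, stance fraction,
#' anthropometrics and the early-stance loading style.
#'
#' @param group `"young"` or `"older"`.
#' @param norm_stride_mean,norm_stride_cv Mean and CV of stride length /
#'   height.
#' @param norm_mtc_mean,norm_mtc_cv Mean and CV of minimum toe clearance /
#'   height.
#' @param cadence Strides per second per foot.
#' @param stance_fraction Fraction of the stride spent in stance (0.4--0.8).
#' @param height_mean,height_sd Height distribution, m.
#' @param mass_mean,mass_sd Body-mass distribution, kg.
#' @param contact_style `"heel_first"` (young) or `"flat"` (older): controls
#'   how early-stance load is shared between the heel and forefoot sensors.
#' @return A `gait_profile` list.
#' @export
gait_profile <- function(group, norm_stride_mean, norm_stride_cv,
                         norm_mtc_mean, norm_mtc_cv, cadence = 0.9,
                         stance_fraction = 0.6, height_mean, height_sd,
                         mass_mean, mass_sd,
                         contact_style = c("heel_first", "flat")) {
  contact_style <- match.arg(contact_style)
  stopifnot(norm_stride_mean > 0, norm_mtc_mean > 0, cadence > 0,
            norm_stride_cv >= 0, norm_mtc_cv >= 0,
            stance_fraction > 0.4, stance_fraction < 0.8,
            height_mean > 0, mass_mean > 0)
  structure(list(group = group, norm_stride_mean = norm_stride_mean,
                 norm_stride_cv = norm_stride_cv,
                 norm_mtc_mean = norm_mtc_mean, norm_mtc_cv = norm_mtc_cv,
                 cadence = cadence, stance_fraction = stance_fraction,
                 height_mean = height_mean, height_sd = height_sd,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 contact_style = contact_style),
            class = "gait_profile")
}

#' Default young- and older-adult gait profiles
#'
#' Defaults encode the cohort statistics reported for straight-line walking:
#' height-normalized stride length 0.670 (CV 0.0534) for young and 0.655
#' (CV 0.0858) for older adults; height-normalized minimum toe clearance
#' 0.0196 (CV 0.30) for young and 0.0120 (CV 0.71) for older adults.
#' Anthropometrics follow the cohorts (young 1.67 +/- 0.066 m,
#' 60.2 +/- 16.6 kg; older 1.54 +/- 0.054 m, 54.6 +/- 7.9 kg). Older adults
#' contact the ground in a flatter orientation, shifting early-stance load
#' toward the toe and metatarsals.
#'
#' @return List with elements `young` and `older`, each a [gait_profile()].
#' @export
default_profiles <- function() {
  list(young = gait_profile("young", 0.670, 0.0534, 0.0196, 0.30,
                            height_mean = 1.67, height_sd = 0.066,
                            mass_mean = 60.2, mass_sd = 16.6,
                            contact_style = "heel_first"),
       older = gait_profile("older", 0.655, 0.0858, 0.0120, 0.71,
                            height_mean = 1.54, height_sd = 0.054,
                            mass_mean = 54.6, mass_sd = 7.9,
                            contact_style = "flat"))
}

#' Sensor noise / error model
#'
#' @param accel_noise_sd Accelerometer white-noise sd, m/s^2.
#' @param accel_gain_error True per-axis accelerometer gains (the emitted
#'   reading is divided by these, so calibration must recover them).
#' @param accel_bias True per-axis accelerometer biases, m/s^2 (added to the
#'   emitted reading).
#' @param force_noise_sd Force-channel white-noise sd, N.
#' @param quat_angle_noise_sd Quaternion orientation noise sd, degrees.
#' @param posture_noise_sd Noise of stationary calibration postures, m/s^2.
#' @return A `sensor_noise` list.
#' @export
sensor_noise <- function(accel_noise_sd = 0.05,
                         accel_gain_error = c(1.02, 0.98, 1.01),
                         accel_bias = c(0.10, -0.05, 0.08),
                         force_noise_sd = 1.0,
                         quat_angle_noise_sd = 0.2,
                         posture_noise_sd = 0.02) {
  stopifnot(accel_noise_sd >= 0, force_noise_sd >= 0,
            quat_angle_noise_sd >= 0, all(accel_gain_error > 0))
  structure(list(accel_noise_sd = accel_noise_sd,
                 accel_gain_error = accel_gain_error,
                 accel_bias = accel_bias, force_noise_sd = force_noise_sd,
                 quat_angle_noise_sd = quat_angle_noise_sd,
                 posture_noise_sd = posture_noise_sd),
            class = "sensor_noise")
}

#' Noise-free sensor model
#' @return A `sensor_noise` with all errors zero and gains one.
#' @export
no_noise <- function() {
  sensor_noise(accel_noise_sd = 0, accel_gain_error = c(1, 1, 1),
               accel_bias = c(0, 0, 0), force_noise_sd = 0,
               quat_angle_noise_sd = 0, posture_noise_sd = 0)
}

#' Draw per-stride gait parameters for one participant
#'
#' Height and mass are Normal; per-stride stride length is Normal with mean
#' `norm_stride_mean * height` and sd `cv * mean` (truncated above 0.2 m);
#' per-stride minimum toe clearance is lognormal with mean
#' `norm_mtc_mean * height` and the profile CV. The lognormal keeps the MTC
#' support positive without the moment distortion a hard-truncated Normal
#' would introduce at the large CVs of the older cohort (see the methods
#' vignette); draws below 0.001 m are resampled to that floor.
#'
#' @param profile A [gait_profile()].
#' @param n_strides Number of strides (>= 1).
#' @param rng_seed Integer seed; identical seeds give identical draws.
#' @return List with `height`, `mass` and data.frame `strides`
#'   (`stride_length_m`, `mtc_m`).
#' @export
sample_strides <- function(profile, n_strides, rng_seed) {
  stopifnot(n_strides >= 1)
  withr::local_seed(rng_seed)
  height <- stats::rnorm(1, profile$height_mean, profile$height_sd)
  height <- min(max(height, 1.3), 2.1)
  mass <- stats::rnorm(1, profile$mass_mean, profile$mass_sd)
  mass <- min(max(mass, 35), 120)
  sl_mean <- profile$norm_stride_mean * height
  sl <- stats::rnorm(n_strides, sl_mean, profile$norm_stride_cv * sl_mean)
  sl <- pmax(sl, 0.2)
  mtc_mean <- profile$norm_mtc_mean * height
  cv <- profile$norm_mtc_cv
  sdlog <- sqrt(log(1 + cv^2))
  mtc <- stats::rlnorm(n_strides, log(mtc_mean) - sdlog^2 / 2, sdlog)
  mtc <- pmax(mtc, 0.001)
  list(height = height, mass = mass,
       strides = data.frame(stride_length_m = sl, mtc_m = mtc))
}

# minimum-jerk unit step and its second derivative
minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5
minjerk_dd <- function(u) 60 * u - 180 * u^2 + 120 * u^3

# C2 piecewise curve through knots with zero slope and curvature at every
# knot: each segment is a monotone minimum-jerk step between knot values, so
# knot values are attained exactly. Returns value and second derivative in u.
pw_minjerk <- function(u, knots_u, knots_v) {
  m <- length(knots_u) - 1L
  j <- pmin(pmax(findInterval(u, knots_u, rightmost.closed = TRUE), 1L), m)
  w <- knots_u[j + 1L] - knots_u[j]
  uu <- (u - knots_u[j]) / w
  dv <- knots_v[j + 1L] - knots_v[j]
  list(value = knots_v[j] + dv * minjerk(uu),
       dd = dv * minjerk_dd(uu) / w^2)
}

# Clearance curve over one swing, u in [0,1]: two-peak path through
# (h0, 3M, M, 2M, h0) at u = 0, .25, .5, .75, 1, so the mid-swing dip equals
# the requested MTC exactly and is a strict local minimum.
clearance_shape <- function(u, mtc, h0) {
  pw_minjerk(u, c(0, 0.25, 0.5, 0.75, 1),
             c(h0, 3 * mtc, mtc, 2 * mtc, h0))
}

# pitch bump over one swing (degrees): quartic window, zero value/slope at
# the swing boundaries
pitch_shape <- function(u, amp_deg) amp_deg * 16 * u^2 * (1 - u)^2

#' Build the gait-cycle timing and per-stride segment table of a session
#'
#' A session is: 1 s stationary lead-in, then for each stride a swing segment
#' followed by a flat-foot (stance) segment, then a 1 s stationary lead-out.
#'
#' @param strides Data.frame with `stride_length_m`, `mtc_m` per stride.
#' @param cadence Strides per second.
#' @param stance_fraction Stance fraction of the stride period.
#' @param lead_s Stationary lead-in/lead-out duration, s.
#' @return Data.frame, one row per stride: timing, stride parameters and the
#'   cumulative forward position at swing start.
#' @keywords internal
stride_schedule <- function(strides, cadence, stance_fraction, lead_s = 1.0) {
  n <- nrow(strides)
  t_stride <- 1 / cadence
  t_swing <- (1 - stance_fraction) * t_stride
  t_stance <- stance_fraction * t_stride
  swing_start <- lead_s + (seq_len(n) - 1L) * t_stride
  data.frame(stride_index = seq_len(n),
             swing_start = swing_start,
             swing_end = swing_start + t_swing,
             flat_start = swing_start + t_swing,
             flat_end = swing_start + t_stride,
             stride_length_m = strides$stride_length_m,
             mtc_m = strides$mtc_m,
             y_start = c(0, cumsum(strides$stride_length_m))[seq_len(n)])
}

# Evaluate the toe (IMU) trajectory of a scheduled session at times t:
# world position (x lateral = 0, y forward, z = clearance above ground),
# world acceleration (analytic second derivatives) and pitch angle (deg,
# rotation about the foot-width axis).
eval_trajectory <- function(t, sched, h0, pitch_amp_deg) {
  n <- length(t)
  y <- numeric(n); z <- rep(h0, n)
  ay <- numeric(n); az <- numeric(n); pitch <- numeric(n)
  total_y <- sum(sched$stride_length_m)
  after <- t >= sched$flat_end[nrow(sched)]
  y[after] <- total_y
  for (k in seq_len(nrow(sched))) {
    s <- sched[k, ]
    tw <- s$swing_end - s$swing_start
    in_sw <- t >= s$swing_start & t < s$swing_end
    if (any(in_sw)) {
      u <- (t[in_sw] - s$swing_start) / tw
      y[in_sw] <- s$y_start + s$stride_length_m * minjerk(u)
      ay[in_sw] <- s$stride_length_m * minjerk_dd(u) / tw^2
      cs <- clearance_shape(u, s$mtc_m, h0)
      z[in_sw] <- cs$value
      az[in_sw] <- cs$dd / tw^2
      pitch[in_sw] <- pitch_shape(u, pitch_amp_deg)
    }
    in_fl <- t >= s$flat_start & t < s$flat_end
    y[in_fl] <- s$y_start + s$stride_length_m
  }
  list(x = numeric(n), y = y, z = z,
       ax = numeric(n), ay = ay, az = az, pitch = pitch)
}

#' Toe trajectory for a single stride
#'
#' Generates the ground-truth toe path of one stride on a regular grid:
#' stationary flat foot, then a swing whose forward displacement follows a
#' minimum-jerk profile reaching the stride length and whose clearance
#' follows a smooth two-peak curve (early peak 3x MTC, mid-swing dip equal to
#' the requested MTC, late peak 2x MTC) returning to the mounting height.
#'
#' @param stride_length_m Stride length, m.
#' @param mtc_m Minimum toe clearance at the mid-swing dip, m.
#' @param dt Sample spacing, s (> 0).
#' @param cadence,stance_fraction Timing parameters (see [gait_profile()]).
#' @param initial_height IMU mounting height, m.
#' @param pitch_amp_deg Pitch-bump amplitude, degrees.
#' @return List with `trace` (data.frame `time, x, y, z, ay, az, pitch_deg`;
#'   `z` is the clearance above ground) and `truth` (stride length, MTC,
#'   swing span).
#' @export
toe_trajectory <- function(stride_length_m, mtc_m, dt = 0.002,
                           cadence = 0.9, stance_fraction = 0.6,
                           initial_height = 0.03, pitch_amp_deg = -18) {
  stopifnot(dt > 0)
  sched <- stride_schedule(data.frame(stride_length_m = stride_length_m,
                                      mtc_m = mtc_m),
                           cadence, stance_fraction, lead_s = 0.5)
  t_end <- sched$flat_end[1L] + 0.5
  t <- seq(0, t_end, by = dt)
  tr <- eval_trajectory(t, sched, initial_height, pitch_amp_deg)
  list(trace = data.frame(time = t, x = tr$x, y = tr$y, z = tr$z,
                          ay = tr$ay, az = tr$az, pitch_deg = tr$pitch),
       truth = data.frame(stride_length_m = stride_length_m, mtc_m = mtc_m,
                          swing_start = sched$swing_start,
                          swing_end = sched$swing_end))
}

#' Synthesize an IMU stream from a scheduled session
#'
#' The world acceleration (analytic second derivative of the toe path) plus
#' gravity is rotated into the IMU-local frame by the trajectory pitch,
#' corrupted by the inverse sensor calibration (divide by gain, add bias) and
#' white noise, and emitted at the IMU rate together with orientation
#' quaternions carrying small random angle errors.
#'
#' @param sched Stride schedule (internal; see [simulate_session()]).
#' @param noise A [sensor_noise()].
#' @param imu_rate Sampling rate, Hz.
#' @param duration Session duration, s.
#' @param initial_height IMU mounting height, m.
#' @param pitch_amp_deg Swing pitch amplitude, deg.
#' @param t_offset Clock phase offset of the first sample, s.
#' @return An [imu_stream()].
#' @keywords internal
synthesize_imu <- function(sched, noise, imu_rate, duration,
                           initial_height, pitch_amp_deg, t_offset = 0) {
  t <- seq(t_offset, duration, by = 1 / imu_rate)
  tr <- eval_trajectory(t, sched, initial_height, pitch_amp_deg)
  n <- length(t)
  g <- 9.81
  accel <- matrix(NA_real_, n, 3L)
  quat <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    a_world <- c(tr$ax[i], tr$ay[i], tr$az[i] + g)
    R <- rot_x(deg2rad(tr$pitch[i]))   # local -> world
    a_local <- crossprod(R, a_world)   # R^T
    accel[i, ] <- a_local / noise$accel_gain_error + noise$accel_bias +
      stats::rnorm(3L, 0, noise$accel_noise_sd)
    q <- quat_from_axis_angle(c(1, 0, 0), deg2rad(tr$pitch[i]))
    if (noise$quat_angle_noise_sd > 0) {
      ax <- stats::rnorm(3L)
      qe <- quat_from_axis_angle(ax, deg2rad(
        stats::rnorm(1L, 0, noise$quat_angle_noise_sd)))
      q <- quat_multiply(qe, q)
    }
    quat[i, ] <- q
  }
  imu_stream(t, accel, quat)
}

# --- force synthesis ---------------------------------------------------------

# vertical load over stance in body-weight units, u in [0,1]: fast loading
# to a 1.1 BW peak, mid-stance valley 0.85 BW, second 1.1 BW peak, unloading
# to zero; mean over stance ~0.87 BW so the stance impulse matches body
# weight x stance duration to within the usual walking range
vertical_shape <- function(u) {
  pw_minjerk(u, c(0, 0.12, 0.5, 0.88, 1),
             c(0, 1.1, 0.85, 1.1, 0))$value
}

# smoothstep ramp for standing weight transfer
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# sensor weight curves over stance progress u; rows heel, mt1, mt5, toe
sensor_weights <- function(u, style) {
  gs <- function(c, w) exp(-(u - c)^2 / (2 * w^2))
  w <- if (style == "heel_first") {
    rbind(1.2 * gs(0.15, 0.18),
          0.5 * gs(0.75, 0.22),
          0.8 * gs(0.50, 0.25),
          1.0 * gs(0.85, 0.15))
  } else {  # flat contact: early load shifted to toe and metatarsals
    rbind(0.7 * gs(0.20, 0.20),
          0.6 * gs(0.70, 0.25),
          1.0 * gs(0.45, 0.28),
          1.0 * gs(0.80, 0.20) + 0.35 * gs(0.10, 0.12))
  }
  sweep(w, 2L, colSums(w), "/")
}

#' Synthesize the localized force stream of a scheduled session
#'
#' Total vertical force in each walking stance follows a double-bump curve
#' peaking at ~1.1 body weight with a mid-stance valley; the
#' anterior-posterior force is a braking-then-propulsion biphasic curve; a
#' small mediolateral component is added. The totals are distributed across
#' the four sensors with style-dependent weights (heel-first loads the heel
#' early; flat contact shifts early load toward the toe and metatarsals),
#' rotated into the sensor-local frame by the inverse of the ground-frame
#' rotation, and corrupted with white noise. Standing phases carry half body
#' weight with smooth weight-transfer ramps.
#'
#' @inheritParams synthesize_imu
#' @param mass Body mass, kg.
#' @param style Contact style, `"heel_first"` or `"flat"`.
#' @param force_rate Sampling rate, Hz.
#' @return A [force_stream()].
#' @keywords internal
synthesize_forces <- function(sched, mass, style, noise, force_rate,
                              duration, initial_height, pitch_amp_deg,
                              t_offset = 0) {
  t <- seq(t_offset, duration, by = 1 / force_rate)
  n <- length(t)
  bw <- mass * 9.81
  ftot <- matrix(0, n, 3L)  # ground frame totals: x, y, z
  wgt <- matrix(0, 4L, n)
  # standing lead-in: half body weight, released over the last 0.15 s
  lead_end <- sched$swing_start[1L]
  in_lead <- t < lead_end
  rel <- smoothstep((lead_end - t[in_lead]) / 0.15)
  ftot[in_lead, 3L] <- 0.5 * bw * rel
  wgt[, in_lead] <- c(0.4, 0.2, 0.2, 0.2)
  # standing lead-out: half body weight, loaded over the first 0.15 s
  out_start <- sched$flat_end[nrow(sched)]
  in_out <- t >= out_start
  lod <- smoothstep((t[in_out] - out_start) / 0.15)
  ftot[in_out, 3L] <- 0.5 * bw * lod
  wgt[, in_out] <- c(0.4, 0.2, 0.2, 0.2)
  # walking stances
  for (k in seq_len(nrow(sched))) {
    s <- sched[k, ]
    in_st <- t >= s$flat_start & t < s$flat_end
    if (!any(in_st)) next
    u <- (t[in_st] - s$flat_start) / (s$flat_end - s$flat_start)
    ftot[in_st, 3L] <- bw * vertical_shape(u)
    ftot[in_st, 2L] <- -0.18 * bw * sin(2 * pi * u)
    ftot[in_st, 1L] <- 0.05 * bw * sin(pi * u) * cos(2 * pi * u)
    wgt[, in_st] <- sensor_weights(u, style)
  }
  # distribute to sensors and rotate ground -> sensor-local (pitch is zero
  # whenever the foot is loaded, but apply the exact inverse rotation anyway)
  tr <- eval_trajectory(t, sched, initial_height, pitch_amp_deg)
  th <- deg2rad(tr$pitch)
  ct <- cos(th); st <- sin(th)
  forces <- matrix(0, n, 12L)
  for (i in 1:4) {
    fx <- wgt[i, ] * ftot[, 1L]
    fy <- wgt[i, ] * ftot[, 2L]
    fz <- wgt[i, ] * ftot[, 3L]
    # inverse of Ry(phi) Rx(theta) with phi = 0: Rx(-theta)
    forces[, 3L * i - 2L] <- fx
    forces[, 3L * i - 1L] <- ct * fy + st * fz
    forces[, 3L * i] <- -st * fy + ct * fz
  }
  if (noise$force_noise_sd > 0)
    forces <- forces + stats::rnorm(n * 12L, 0, noise$force_noise_sd)
  force_stream(t, forces)
}

#' Synthesize stationary calibration postures
#'
#' Readings of gravity in random stationary orientations, corrupted by the
#' same inverse gain/bias model as the IMU stream plus posture noise.
#'
#' @param noise A [sensor_noise()].
#' @param n_postures Number of postures. Default 20.
#' @return n x 3 matrix of raw acceleration readings, m/s^2.
#' @export
synthesize_postures <- function(noise, n_postures = 20L) {
  dirs <- matrix(stats::rnorm(3L * n_postures), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  readings <- 9.81 * dirs
  readings <- sweep(readings, 2L, noise$accel_gain_error, "/")
  readings <- sweep(readings, 2L, noise$accel_bias, "+")
  readings + stats::rnorm(length(readings), 0, noise$posture_noise_sd)
}

#' Simulate a complete walking session
#'
#' Generates one participant's straight-line walking session: stride
#' parameters drawn from the group profile, toe trajectory, IMU stream
#' (asynchronous ~70 Hz clock), localized force stream (~400 Hz clock),
#' stationary calibration postures, session metadata and the ground truth.
#'
#' @param profile A [gait_profile()].
#' @param n_strides Number of strides.
#' @param seed Integer seed; all randomness in the session derives from it.
#' @param noise A [sensor_noise()]. Default [sensor_noise()].
#' @param participant_id Identifier for the metadata.
#' @param shoe_side `"left"` or `"right"`.
#' @param imu_rate,force_rate Sampling rates, Hz.
#' @param imu_initial_height IMU mounting height, m.
#' @return A `sim_session` list: `meta`, `force`, `imu`, `postures`,
#'   `truth` (per-stride truth table) and `profile`.
#' @export
simulate_session <- function(profile, n_strides, seed,
                             noise = sensor_noise(),
                             participant_id = "sim", shoe_side = "left",
                             imu_rate = 70, force_rate = 400,
                             imu_initial_height = 0.03) {
  draws <- sample_strides(profile, n_strides, seed)
  withr::local_seed(seed + 1L)
  sched <- stride_schedule(draws$strides, profile$cadence,
                           profile$stance_fraction)
  duration <- sched$flat_end[nrow(sched)] + 1.0
  pitch_amp <- if (profile$contact_style == "heel_first") -18 else -8
  imu_offset <- stats::runif(1, 0, 1 / imu_rate)
  imu <- synthesize_imu(sched, noise, imu_rate, duration,
                        imu_initial_height, pitch_amp, imu_offset)
  force <- synthesize_forces(sched, draws$mass, profile$contact_style,
                             noise, force_rate, duration,
                             imu_initial_height, pitch_amp)
  postures <- synthesize_postures(noise)
  meta <- session_meta(participant_id, profile$group, draws$height,
                       draws$mass, shoe_side, force_rate, imu_rate,
                       imu_initial_height)
  truth <- cbind(sched[c("stride_index", "swing_start", "swing_end",
                         "flat_start", "flat_end", "stride_length_m",
                         "mtc_m")])
  structure(list(meta = meta, force = force, imu = imu, postures = postures,
                 truth = truth, profile = profile),
            class = "sim_session")
}

#' Write / read a simulated session directory
#'
#' A session directory holds `force.csv`, `imu.csv`, `meta.yaml`,
#' `postures.csv` and `truth.csv`.
#'
#' @param session A `sim_session` from [simulate_session()].
#' @param dir Directory path (created if missing).
#' @return `dir` (write) or a `sim_session`-like list (read; `profile` is
#'   not stored and comes back `NULL`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sensor_log(session$force, file.path(dir, "force.csv"))
  write_sensor_log(session$imu, file.path(dir, "imu.csv"))
  write_session_meta(session$meta, file.path(dir, "meta.yaml"))
  post <- as.data.frame(session$postures)
  names(post) <- c("ax", "ay", "az")
  utils::write.csv(format(post, digits = 17, trim = TRUE),
                   file.path(dir, "postures.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(format(session$truth, digits = 17, trim = TRUE),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  post <- utils::read.csv(file.path(dir, "postures.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  structure(list(meta = read_session_meta(file.path(dir, "meta.yaml")),
                 force = read_force_log(file.path(dir, "force.csv")),
                 imu = read_imu_log(file.path(dir, "imu.csv")),
                 postures = as.matrix(post), truth = truth, profile = NULL),
            class = "sim_session")
}
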