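#' Analyze one recorded session end to end
#'
#' Runs the full shoe-sensor processing chain on a session (simulated or
#' loaded from disk):
#'
#' 1. accelerometer calibration, fitted from the session's stationary
#'    postures when present (gains/biases recovered by Gauss-Newton);
#' 2. initial attitude from the stationary lead-in (gravity-consistent
#'    z-y-x initialization) and Euler-angle accumulation from the quaternion
#'    stream;
#' 3. kinematics branch: global-frame acceleration with gravity removal and
#'    `min(40, 0.45 fs)` Hz low-pass, flat-foot detection (on the unfiltered
#'    gravity-removed signal), stride segmentation, ZUPT double integration
#'    with piecewise-linear drift cancellation, stride length, toe clearance
#'    and minimum toe clearance;
#' 4. GRF branch: 50 Hz low-pass, offset removal over unloaded samples,
#'    Euler-angle interpolation onto the force clock, rotation into the
#'    ground frame, 15 N stance detection, 101-point normalization, segment
#'    summaries and sensor contribution percentages.
#'
#' @param session A `sim_session` (from [simulate_session()] or
#'   [read_session()]), or any list with `meta`, `force`, `imu` and
#'   optionally `postures`.
#' @param stance_threshold_n Stance detection threshold, N. Default 15.
#' @param stationary_window_s Length of the lead-in used for the initial
#'   attitude, s. Default 0.5.
#' @param grf Run the GRF branch (default `TRUE`); the kinematics branch
#'   always runs.
#' @return A `gait_analysis` list: `calibration`, `orientation`,
#'   `strides` (stride-record table with clearance traces attached),
#'   `stances` (list of `normalized_stance`), `segment_summary`,
#'   `contributions` (per-stance list), `participant` (one-row summary),
#'   `meta`.
#' @export
analyze_session <- function(session, stance_threshold_n = 15,
                            stationary_window_s = 0.5, grf = TRUE) {
  meta <- session$meta
  imu <- session$imu

  cal <- if (!is.null(session$postures)) {
    fit_calibration(session$postures)
  } else {
    identity_calibration()
  }
  acc_cal <- apply_calibration(cal, as.matrix(imu[, c("ax", "ay", "az")]))
  imu_cal <- imu
  imu_cal$ax <- acc_cal[, 1L]; imu_cal$ay <- acc_cal[, 2L]
  imu_cal$az <- acc_cal[, 3L]

  # initial attitude from the stationary lead-in
  sel <- imu_cal$time <= imu_cal$time[1L] + stationary_window_s
  a0 <- colMeans(acc_cal[sel, , drop = FALSE])
  init <- initial_angles_gravity(a0)
  orient <- accumulate_orientation(imu_cal, init)

  # kinematics branch: the band-passed signal feeds the integrator, while
  # flat-foot detection uses the unfiltered gravity-removed signal (the
  # 1 Hz high-pass smears swing bursts into the flat windows, masking them)
  acc_glob <- to_global_accel(imu_cal, orient, filter = "lowpass")
  acc_raw <- to_global_accel(imu_cal, orient, filter = "none")
  mask <- detect_flat_foot(imu_cal, acc_raw)
  strides_tbl <- segment_strides(mask)
  zupt <- integrate_with_zupt(acc_glob, strides_tbl)
  records <- stride_records(zupt, acc_glob$time, meta$imu_initial_height)

  stances <- list(); contrib <- list(); seg_sum <- NULL
  if (grf) {
    fs_force <- 1 / stats::median(diff(session$force$time))
    filt <- lowpass_forces(session$force, fs_force)
    pre <- detect_stance_phases(filt, stance_threshold_n)
    loaded <- rep(FALSE, nrow(filt))
    for (k in seq_len(nrow(pre))) loaded[pre$start_idx[k]:pre$end_idx[k]] <- TRUE
    filt <- remove_offsets(filt, !loaded)
    ang_f <- interpolate_orientation_to_force_clock(orient, filt$time)
    grf_ground <- transform_to_ground(filt, ang_f)
    phases <- detect_stance_phases(grf_ground, stance_threshold_n)
    # standing lead-in/lead-out are not gait: drop stances that do not
    # overlap a detected stride
    t0 <- acc_glob$time[strides_tbl$start_idx[1L]]
    t1 <- acc_glob$time[strides_tbl$end_idx[nrow(strides_tbl)]]
    gait <- grf_ground$time[phases$start_idx] >= t0 - 0.2 &
      grf_ground$time[phases$end_idx] <= t1 + 0.2
    phases <- phases[gait, , drop = FALSE]
    stances <- lapply(seq_len(nrow(phases)),
                      function(k) normalize_stance(grf_ground, phases[k, ]))
    if (length(stances)) {
      seg_sum <- segment_summary(stances, meta$body_mass)
      contrib <- lapply(stances, contribution_percent)
    }
  }

  structure(list(calibration = cal, orientation = orient,
                 strides = records, stances = stances,
                 segment_summary = seg_sum, contributions = contrib,
                 participant = participant_summary(records, meta),
                 meta = meta),
            class = "gait_analysis")
}

#' Simulate and analyze a cohort of participants
#'
#' Convenience driver for group-level studies: simulates `n_participants`
#' sessions from one profile and runs [analyze_session()] on each.
#'
#' @param profile A [gait_profile()].
#' @param n_participants Number of participants.
#' @param n_strides Strides per participant.
#' @param seed Base seed; participant k uses `seed + k`.
#' @param noise A [sensor_noise()].
#' @param grf Run the GRF branch per participant (default `FALSE`; the
#'   kinematic parameters do not need it and it dominates runtime).
#' @return List with `summaries` (row-bound participant summaries) and
#'   `analyses` (list of `gait_analysis`), plus `truths` (list of truth
#'   tables).
#' @export
simulate_cohort <- function(profile, n_participants, n_strides, seed,
                            noise = sensor_noise(), grf = FALSE) {
  analyses <- vector("list", n_participants)
  truths <- vector("list", n_participants)
  for (k in seq_len(n_participants)) {
    ses <- simulate_session(profile, n_strides, seed + k, noise,
                            participant_id = sprintf("%s%02d",
                                                     profile$group, k))
    analyses[[k]] <- analyze_session(ses, grf = grf)
    truths[[k]] <- ses$truth
  }
  list(summaries = do.call(rbind, lapply(analyses, `[[`, "participant")),
       analyses = analyses, truths = truths)
}
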