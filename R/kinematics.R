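#' Rotate IMU accelerations into the global frame and remove gravity
#'
#' Per IMU sample the calibrated local acceleration is rotated with
#' `Rz(psi) Ry(phi) Rx(theta)`, gravity `(0, 0, 9.81)` is subtracted, and the
#' result is band-pass filtered (1.0 Hz to `min(40, 0.45 fs)` Hz, zero-phase)
#' to suppress residual gravity leakage and high-frequency noise before
#' integration.
#'
#' @param imu An [imu_stream()] (acceleration columns already calibrated).
#' @param orientation An `orientation_trace` on the IMU clock, same length.
#' @param filter `"bandpass"` (default), `"lowpass"` (upper corner only;
#'   used by the analysis pipeline ahead of ZUPT integration, which supplies
#'   its own low-frequency drift control -- see the methods vignette) or
#'   `"none"`.
#' @return A `global_accel` object: list with `time` and `accel`
#'   (n x 3 matrix, m/s^2, gravity removed).
#' @export
to_global_accel <- function(imu, orientation,
                            filter = c("bandpass", "lowpass", "none")) {
  filter <- match.arg(filter)
  n <- nrow(imu)
  if (nrow(orientation) != n)
    stop("orientation must be on the IMU clock", call. = FALSE)
  a <- as.matrix(imu[, c("ax", "ay", "az")])
  th <- deg2rad(orientation$theta)
  ph <- deg2rad(orientation$phi)
  ps <- deg2rad(orientation$psi)
  ct <- cos(th); st <- sin(th); cp <- cos(ph); sp <- sin(ph)
  cs <- cos(ps); ss <- sin(ps)
  # Rz Ry Rx expanded row-wise
  y1 <- ct * a[, 2L] - st * a[, 3L]
  z1 <- st * a[, 2L] + ct * a[, 3L]
  x2 <- cp * a[, 1L] + sp * z1
  z2 <- -sp * a[, 1L] + cp * z1
  gx <- cs * x2 - ss * y1
  gy <- ss * x2 + cs * y1
  gz <- z2 - 9.81
  g <- cbind(gx, gy, gz)
  colnames(g) <- c("ax", "ay", "az")
  if (filter != "none") {
    fs <- 1 / stats::median(diff(imu$time))
    if (filter == "bandpass") {
      g <- bandpass_accel(g, fs)
    } else {
      lp <- butter_lowpass(min(40, 0.45 * fs), fs)
      for (j in 1:3) g[, j] <- zero_phase(lp, g[, j])
    }
  }
  structure(list(time = imu$time, accel = g), class = "global_accel")
}

#' Detect flat-foot phases
#'
#' A sample belongs to a flat-foot phase when the raw acceleration norm lies
#' within `9.81 +/- accel_band` m/s^2 (quasi-static reading) and the norm of
#' the band-passed global acceleration is below `dyn_thresh` m/s^2 (no
#' residual dynamics), sustained for at least `min_flat` seconds. Flat-foot
#' phases are the zero-velocity anchors for ZUPT integration.
#'
#' @param imu An [imu_stream()] (calibrated).
#' @param accel_global A `global_accel` from [to_global_accel()].
#' @param accel_band Half-width of the static-norm band, m/s^2. Default 0.8.
#' @param dyn_thresh Dynamic-norm threshold, m/s^2. Default 1.0.
#' @param min_flat Minimum sustained duration, s. Default 0.05.
#' @return Logical vector (the flat-foot mask) with attribute `runs`, a
#'   data.frame of run `start_idx`/`end_idx`.
#' @export
detect_flat_foot <- function(imu, accel_global, accel_band = 0.8,
                             dyn_thresh = 1.0, min_flat = 0.05) {
  n <- nrow(imu)
  if (length(accel_global$time) != n)
    stop("streams not aligned", call. = FALSE)
  raw_norm <- sqrt(imu$ax^2 + imu$ay^2 + imu$az^2)
  dyn_norm <- sqrt(rowSums(accel_global$accel^2))
  cand <- abs(raw_norm - 9.81) < accel_band & dyn_norm < dyn_thresh
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- stats::median(diff(imu$time))
  ok <- r$values & (r$lengths - 1L) * dt >= min_flat
  mask <- rep(FALSE, n)
  runs <- data.frame(start_idx = starts[ok], end_idx = ends[ok])
  for (k in seq_len(nrow(runs)))
    mask[runs$start_idx[k]:runs$end_idx[k]] <- TRUE
  if (!nrow(runs))
    stop("no flat-foot phase found in the trial", call. = FALSE)
  attr(mask, "runs") <- runs
  mask
}

#' Segment the trial into strides
#'
#' One stride spans from the midpoint of one flat-foot run to the midpoint of
#' the next, so integration drift cannot accumulate across strides. The end
#' of a stride's opening flat-foot run is recorded as the swing start.
#'
#' @param mask Flat-foot mask from [detect_flat_foot()] (with `runs`
#'   attribute).
#' @return Data.frame `start_idx, end_idx, swing_start_idx, swing_end_idx`
#'   (IMU-clock sample indices), one row per stride.
#' @export
segment_strides <- function(mask) {
  runs <- attr(mask, "runs")
  if (is.null(runs) || nrow(runs) < 2L)
    stop("need at least two flat-foot runs to segment strides",
         call. = FALSE)
  mid <- as.integer(round((runs$start_idx + runs$end_idx) / 2))
  k <- nrow(runs) - 1L
  data.frame(start_idx = mid[seq_len(k)],
             end_idx = mid[seq_len(k) + 1L],
             swing_start_idx = runs$end_idx[seq_len(k)],
             swing_end_idx = runs$start_idx[seq_len(k) + 1L])
}

#' ZUPT double integration with piecewise-linear drift cancellation
#'
#' Per stride and axis the global acceleration is integrated (trapezoidal
#' rule) from zero initial velocity. The residual end-of-stride velocity --
#' which should be zero at the closing flat foot -- is treated as linearly
#' accumulated drift and removed by subtracting the ramp
#' `v_err * (t - t0) / (t1 - t0)`. The corrected velocity is integrated to
#' position; the vertical position is additionally corrected to zero
#' displacement at stride end (the foot returns to ground level).
#'
#' @param accel_global A `global_accel`.
#' @param strides Stride table from [segment_strides()].
#' @param min_samples Minimum IMU samples per stride. Default 5.
#' @return List of per-stride lists, each with `time`, `velocity`
#'   (n x 3), `position` (n x 3), `drift_velocity` (3-vector removed) and the
#'   stride-row metadata.
#' @export
integrate_with_zupt <- function(accel_global, strides, min_samples = 5L) {
  out <- vector("list", nrow(strides))
  for (k in seq_len(nrow(strides))) {
    i0 <- strides$start_idx[k]; i1 <- strides$end_idx[k]
    if (i1 - i0 + 1L < min_samples)
      stop("stride shorter than ", min_samples, " samples", call. = FALSE)
    tt <- accel_global$time[i0:i1]
    a <- accel_global$accel[i0:i1, , drop = FALSE]
    ramp <- (tt - tt[1L]) / (tt[length(tt)] - tt[1L])
    v <- apply(a, 2L, function(col) pracma::cumtrapz(tt, col))
    v_err <- v[nrow(v), ]
    v_corr <- v - outer(ramp, v_err)
    p <- apply(v_corr, 2L, function(col) pracma::cumtrapz(tt, col))
    p[, 3L] <- p[, 3L] - ramp * p[nrow(p), 3L]
    out[[k]] <- list(time = tt, velocity = v_corr, position = p,
                     drift_velocity = v_err,
                     start_idx = i0, end_idx = i1,
                     swing_start_idx = strides$swing_start_idx[k],
                     swing_end_idx = strides$swing_end_idx[k])
  }
  out
}

#' Stride length from an integrated horizontal trace
#'
#' Euclidean norm of the horizontal (x, y) displacement accumulated over the
#' stride. Because the foot is stationary during flat-foot phases, the
#' displacement between consecutive swing starts equals the displacement
#' between the stride's flat-foot midpoints.
#'
#' @param position n x 3 (or n x 2 horizontal) per-stride position trace, m.
#' @return Stride length in metres.
#' @export
stride_length <- function(position) {
  position <- as.matrix(position)
  d <- position[nrow(position), 1:2] - position[1L, 1:2]
  sqrt(sum(d^2))
}

#' Toe clearance from the vertical position trace
#'
#' `clearance(t) = z(t) + initial_height`: the vertical IMU travel plus the
#' IMU mounting height above the ground (default 0.03 m). Negative values are
#' retained (not clamped) so integration faults remain visible.
#'
#' @param position_z Drift-corrected vertical position trace, m.
#' @param initial_height IMU mounting height, m. Default 0.03.
#' @return Clearance trace, m.
#' @export
toe_clearance <- function(position_z, initial_height = 0.03) {
  as.numeric(position_z) + initial_height
}

#' Minimum toe clearance in mid-swing
#'
#' Searches the central window (25-75% of the swing duration) of the
#' clearance trace for a local minimum and returns the lowest one; when the
#' trace is monotone within the window, the window's global minimum is
#' returned instead.
#'
#' @param clearance Clearance trace over a stride, m.
#' @param time Sample times matching `clearance`, s.
#' @param swing_span Numeric pair `(swing_start, swing_end)` in seconds.
#' @param window Fractions of the swing delimiting the search window.
#'   Default `c(0.25, 0.75)`.
#' @return Minimum toe clearance, m.
#' @export
minimum_toe_clearance <- function(clearance, time, swing_span,
                                  window = c(0.25, 0.75)) {
  t0 <- swing_span[1L] + window[1L] * diff(swing_span)
  t1 <- swing_span[1L] + window[2L] * diff(swing_span)
  sel <- which(time >= t0 & time <= t1)
  if (!length(sel)) stop("empty mid-swing window", call. = FALSE)
  y <- clearance[sel]
  if (length(y) > 2L) {
    interior <- 2:(length(y) - 1L)
    is_min <- y[interior] <= y[interior - 1L] & y[interior] <= y[interior + 1L]
    if (any(is_min)) return(min(y[interior][is_min]))
  }
  min(y)
}

#' Per-stride kinematic records from an analyzed IMU stream
#'
#' Convenience wrapper running [integrate_with_zupt()] output into stride
#' records: stride length, clearance trace and minimum toe clearance.
#'
#' @param zupt Output of [integrate_with_zupt()].
#' @param accel_time IMU-clock time vector (for swing spans).
#' @param initial_height IMU mounting height, m.
#' @return Data.frame `stride_index, start_time, end_time, stride_length_m,
#'   mtc_m` with the clearance traces attached as attribute
#'   `clearance_traces`.
#' @export
stride_records <- function(zupt, accel_time, initial_height = 0.03) {
  n <- length(zupt)
  traces <- vector("list", n)
  rec <- data.frame(stride_index = seq_len(n), start_time = NA_real_,
                    end_time = NA_real_, stride_length_m = NA_real_,
                    mtc_m = NA_real_)
  for (k in seq_len(n)) {
    z <- zupt[[k]]
    clr <- toe_clearance(z$position[, 3L], initial_height)
    swing <- c(accel_time[z$swing_start_idx], accel_time[z$swing_end_idx])
    rec$start_time[k] <- z$time[1L]
    rec$end_time[k] <- z$time[length(z$time)]
    rec$stride_length_m[k] <- stride_length(z$position)
    rec$mtc_m[k] <- minimum_toe_clearance(clr, z$time, swing)
    traces[[k]] <- data.frame(time = z$time, clearance_m = clr)
  }
  attr(rec, "clearance_traces") <- traces
  rec
}
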