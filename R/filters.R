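# Zero-phase Butterworth filtering with odd-reflection edge padding.
# Padding suppresses the startup transients of signal::filtfilt, so a DC
# signal passes a low-pass filter unchanged to numerical precision.

zero_phase <- function(filt, x) {
  n <- length(x)
  if (n < 8L) stop("signal too short to filter", call. = FALSE)
  npad <- min(n - 1L, 3L * max(length(filt$a), length(filt$b)) * 10L)
  head_pad <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[seq(npad + 1L, npad + n)]
}

butter_lowpass <- function(cutoff_hz, fs, order = 4L) {
  if (fs <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  signal::butter(order, cutoff_hz / (fs / 2), type = "low")
}

butter_highpass <- function(cutoff_hz, fs, order = 4L) {
  if (fs <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  signal::butter(order, cutoff_hz / (fs / 2), type = "high")
}

#' Zero-phase low-pass filter for force channels
#'
#' Applies a fourth-order Butterworth low-pass (default cutoff 50 Hz)
#' forward and backward (zero phase) to each of the 12 force channels, so
#' stance-event timing is not shifted by filter lag.
#'
#' @param force A [force_stream()].
#' @param fs Sampling rate in Hz. Must exceed twice the cutoff.
#' @param cutoff_hz Cutoff frequency, Hz. Default 50.
#' @return A filtered `force_stream`.
#' @export
lowpass_forces <- function(force, fs, cutoff_hz = 50) {
  filt <- butter_lowpass(cutoff_hz, fs)
  out <- force
  for (ch in force_columns()) out[[ch]] <- zero_phase(filt, force[[ch]])
  out
}

#' Band-pass filter for IMU accelerations
#'
#' Fourth-order Butterworth band-pass with corner frequencies 1.0 Hz and
#' `min(40, 0.45 fs)` Hz, applied zero-phase to each axis. The band-pass is
#' realized as a cascade of a fourth-order high-pass and a fourth-order
#' low-pass, which is numerically robust at the very low normalized corner
#' (1 Hz on a 70 Hz clock). The upper corner is clipped below the Nyquist
#' frequency of the IMU clock.
#'
#' @param accel n x 3 matrix of accelerations, m/s^2.
#' @param fs Sampling rate, Hz (> 2).
#' @param low_hz,high_hz Corner frequencies, Hz.
#' @return Filtered n x 3 matrix.
#' @export
bandpass_accel <- function(accel, fs, low_hz = 1.0, high_hz = 40) {
  if (fs <= 2) stop("fs must exceed 2 Hz", call. = FALSE)
  accel <- as.matrix(accel)
  high_hz <- min(high_hz, 0.45 * fs)
  hp <- butter_highpass(low_hz, fs)
  lp <- butter_lowpass(high_hz, fs)
  out <- accel
  for (j in seq_len(ncol(accel)))
    out[, j] <- zero_phase(lp, zero_phase(hp, accel[, j]))
  out
}

#' Remove per-channel offsets using unloaded (swing) samples
#'
#' Subtracts, per force channel, the median of the samples marked as
#' unloaded, where the true force is known to be zero.
#'
#' @param force A [force_stream()].
#' @param swing_mask Logical vector marking unloaded samples; must cover at
#'   least 0.1 s of data.
#' @return Offset-corrected `force_stream`.
#' @export
remove_offsets <- function(force, swing_mask) {
  stopifnot(length(swing_mask) == nrow(force))
  dt <- stats::median(diff(force$time))
  if (sum(swing_mask) * dt < 0.1)
    stop("fewer than 0.1 s of unloaded samples available", call. = FALSE)
  out <- force
  for (ch in force_columns())
    out[[ch]] <- force[[ch]] - stats::median(force[[ch]][swing_mask])
  out
}
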