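deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# --- quaternion helpers (Hamilton convention, scalar first) ------------------

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * axis)
}

# Euler angles (theta about x, phi about y, psi about z) of R = Rz Ry Rx,
# radians. Gimbal guard: |R[3,1]| is clamped to sin(89.9 deg) beyond
# phi = +/-85 deg so increments stay finite near the singularity.
rotmat_to_euler_zyx <- function(R) {
  s <- -R[3, 1]
  guard <- sin(deg2rad(85))
  if (abs(s) > guard) s <- sign(s) * min(abs(s), sin(deg2rad(89.9)))
  phi <- asin(max(-1, min(1, s)))
  theta <- atan2(R[3, 2], R[3, 3])
  psi <- atan2(R[2, 1], R[1, 1])
  c(theta = theta, phi = phi, psi = psi)
}

# --- initial attitude --------------------------------------------------------

#' Initial attitude from a stationary acceleration reading
#'
#' Evaluates the literal initial-angle formulas of the shoe-sensor algorithm:
#' `theta0 = -atan2(a_z0, a_x0)` (about x'), `phi0 =
#' arctan(a_x0 / sqrt(a_y0^2 + a_z0^2))` (about y'), `psi0 = 0` (about z').
#' The reading must be stationary: its norm is checked against
#' 9.81 +/- 0.5 m/s^2.
#'
#' These formulas presuppose a particular IMU mounting convention; for the
#' analysis pipeline the gravity-consistent variant
#' [initial_angles_gravity()] is used instead (see the methods vignette).
#'
#' @param a0 Calibrated stationary acceleration triplet, m/s^2.
#' @return List with `theta0`, `phi0`, `psi0` in degrees.
#' @export
initial_angles <- function(a0) {
  a0 <- as.numeric(a0)
  stopifnot(length(a0) == 3L)
  nrm <- sqrt(sum(a0^2))
  if (abs(nrm - 9.81) > 0.5)
    stop(sprintf("reading norm %.3f outside stationarity band 9.81 +/- 0.5",
                 nrm), call. = FALSE)
  list(theta0 = rad2deg(-atan2(a0[3], a0[1])),
       phi0 = rad2deg(atan(a0[1] / sqrt(a0[2]^2 + a0[3]^2))),
       psi0 = 0)
}

#' Gravity-consistent initial attitude
#'
#' Returns the unique z-y-x attitude (with psi0 = 0) for which the global
#' rotation `Rz(psi) Ry(phi) Rx(theta)` maps the stationary local reading onto
#' `(0, 0, ||a0||)`, i.e. for which gravity subtraction in the global frame
#' cancels exactly at rest: `theta0 = atan2(a_y0, a_z0)`,
#' `phi0 = -atan2(a_x0, sqrt(a_y0^2 + a_z0^2))`.
#'
#' @inheritParams initial_angles
#' @return List with `theta0`, `phi0`, `psi0` in degrees.
#' @export
initial_angles_gravity <- function(a0) {
  a0 <- as.numeric(a0)
  stopifnot(length(a0) == 3L)
  nrm <- sqrt(sum(a0^2))
  if (abs(nrm - 9.81) > 0.5)
    stop(sprintf("reading norm %.3f outside stationarity band 9.81 +/- 0.5",
                 nrm), call. = FALSE)
  list(theta0 = rad2deg(atan2(a0[2], a0[3])),
       phi0 = rad2deg(-atan2(a0[1], sqrt(a0[2]^2 + a0[3]^2))),
       psi0 = 0)
}

#' Orientation trace container
#'
#' @param time Seconds (IMU clock).
#' @param theta,phi,psi Euler angles in degrees about the x', y', z' axes.
#' @return An `orientation_trace` data.frame.
#' @export
orientation_trace <- function(time, theta, phi, psi) {
  structure(data.frame(time = time, theta = theta, phi = phi, psi = psi),
            class = c("orientation_trace", "data.frame"))
}

#' Accumulate Euler angles from the IMU quaternion stream
#'
#' For consecutive samples the relative rotation `q_k * q_{k-1}^-1` is
#' decomposed into intrinsic z-y-x Euler increments (the composition order of
#' the global transform) and the increments are summed onto the running
#' angles, starting from the initial attitude. This keeps per-step increments
#' small so the Euler decomposition is well conditioned, and makes quaternion
#' measurement noise telescope instead of accumulating.
#'
#' @param imu An [imu_stream()].
#' @param init List with `theta0`, `phi0`, `psi0` in degrees (from
#'   [initial_angles_gravity()] or [initial_angles()]).
#' @return An `orientation_trace` on the IMU clock, degrees.
#' @export
accumulate_orientation <- function(imu, init) {
  n <- nrow(imu)
  q <- as.matrix(imu[, c("qw", "qx", "qy", "qz")])
  qn <- sqrt(rowSums(q^2))
  if (any(abs(qn - 1) > 1e-6))
    stop("non-unit quaternion in IMU stream", call. = FALSE)
  ang <- matrix(0, n, 3L)
  ang[1L, ] <- c(init$theta0, init$phi0, init$psi0)
  if (n > 1L) {
    cur <- deg2rad(ang[1L, ])
    for (k in 2:n) {
      q_rel <- quat_multiply(q[k, ], quat_conjugate(q[k - 1L, ]))
      inc <- rotmat_to_euler_zyx(quat_to_rotmat(q_rel))
      cur <- cur + inc
      ang[k, ] <- rad2deg(cur)
    }
  }
  orientation_trace(imu$time, theta = ang[, 1L], phi = ang[, 2L],
                    psi = ang[, 3L])
}

# --- rotation matrices -------------------------------------------------------

rot_x <- function(t) matrix(c(1, 0, 0,
                              0, cos(t), -sin(t),
                              0, sin(t), cos(t)), 3L, byrow = TRUE)
rot_y <- function(t) matrix(c(cos(t), 0, sin(t),
                              0, 1, 0,
                              -sin(t), 0, cos(t)), 3L, byrow = TRUE)
rot_z <- function(t) matrix(c(cos(t), -sin(t), 0,
                              sin(t), cos(t), 0,
                              0, 0, 1), 3L, byrow = TRUE)

#' Ground-frame rotation for localized forces
#'
#' The shoe-local force reading is rotated into the horizontal/vertical
#' ground frame with `R = Ry(phi) Rx(theta)`.
#'
#' @param theta,phi Euler angles in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_ground <- function(theta, phi) {
  stopifnot(is.finite(theta), is.finite(phi))
  rot_y(deg2rad(phi)) %*% rot_x(deg2rad(theta))
}

#' Global-frame rotation for IMU accelerations
#'
#' Local IMU acceleration is rotated into the global frame with
#' `R = Rz(psi) Ry(phi) Rx(theta)`.
#'
#' @param theta,phi,psi Euler angles in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_global <- function(theta, phi, psi) {
  stopifnot(is.finite(theta), is.finite(phi), is.finite(psi))
  rot_z(deg2rad(psi)) %*% rot_y(deg2rad(phi)) %*% rot_x(deg2rad(theta))
}
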