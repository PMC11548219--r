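#' Session metadata
#'
#' Constructs and validates the metadata record describing one recording
#' session of the shoe sensor system: participant descriptors and the nominal
#' sampling rates of the two sensor clocks (force sensors ~400 Hz, toe-mounted
#' IMU ~70 Hz).
#'
#' @param participant_id Character identifier.
#' @param group `"young"` or `"older"`.
#' @param height Participant height in metres (0.5--2.5).
#' @param body_mass Body mass in kg (20--200).
#' @param shoe_side `"left"` or `"right"`.
#' @param force_rate_hz Force-sensor sampling rate in Hz.
#' @param imu_rate_hz IMU sampling rate in Hz.
#' @param imu_initial_height Height of the IMU above the ground when the shoe
#'   is flat on the floor, in metres. Default 0.03 m.
#' @return An object of class `session_meta` (a named list).
#' @export
session_meta <- function(participant_id, group = c("young", "older"),
                         height, body_mass, shoe_side = c("left", "right"),
                         force_rate_hz = 400, imu_rate_hz = 70,
                         imu_initial_height = 0.03) {
  group <- match.arg(group)
  shoe_side <- match.arg(shoe_side)
  stopifnot(is.numeric(height), length(height) == 1L,
            is.numeric(body_mass), length(body_mass) == 1L)
  if (height <= 0.5 || height >= 2.5)
    stop("height must be in (0.5, 2.5) m", call. = FALSE)
  if (body_mass <= 20 || body_mass >= 200)
    stop("body_mass must be in (20, 200) kg", call. = FALSE)
  if (force_rate_hz <= 0 || imu_rate_hz <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  structure(list(participant_id = as.character(participant_id), group = group,
                 height = height, body_mass = body_mass, shoe_side = shoe_side,
                 force_rate_hz = force_rate_hz, imu_rate_hz = imu_rate_hz,
                 imu_initial_height = imu_initial_height),
            class = "session_meta")
}

# column layout of a force log: 4 sensors (heel, MT1, MT5, toe) x 3 axes
force_columns <- function() {
  as.vector(vapply(1:4, function(i) paste0(c("fx", "fy", "fz"), i),
                   character(3)))
}

#' Force stream container
#'
#' A force stream is a data.frame with a strictly increasing `time` column
#' (seconds) and 12 force channels `fx1,fy1,fz1,...,fx4,fy4,fz4` (newtons) in
#' the shoe-local frame: sensors 1--4 are heel, first metatarsal, fifth
#' metatarsal and toe; x' is foot width, y' foot length, z' vertical.
#'
#' @param time Numeric vector of sample times in seconds.
#' @param forces Numeric matrix or data.frame with the 12 channels in the
#'   canonical column order.
#' @return A `force_stream` data.frame.
#' @export
force_stream <- function(time, forces) {
  forces <- as.data.frame(forces)
  if (ncol(forces) != 12L)
    stop("force stream needs 12 channels (4 sensors x 3 axes)", call. = FALSE)
  names(forces) <- force_columns()
  check_time(time, length(forces[[1L]]))
  if (anyNA(forces)) stop("force stream contains NA", call. = FALSE)
  structure(cbind(data.frame(time = time), forces),
            class = c("force_stream", "data.frame"))
}

#' IMU stream container
#'
#' @param time Sample times, seconds, strictly increasing.
#' @param accel n x 3 matrix of local-frame accelerations (m/s^2).
#' @param quat n x 4 matrix of orientation quaternions, scalar first
#'   (w, x, y, z), Hamilton convention; renormalized on construction.
#' @return An `imu_stream` data.frame with columns
#'   `time, ax, ay, az, qw, qx, qy, qz`.
#' @export
imu_stream <- function(time, accel, quat) {
  accel <- as.matrix(accel); quat <- as.matrix(quat)
  stopifnot(ncol(accel) == 3L, ncol(quat) == 4L,
            nrow(accel) == nrow(quat))
  check_time(time, nrow(accel))
  qn <- sqrt(rowSums(quat^2))
  if (any(qn < 1e-3))
    stop("degenerate (near-zero) quaternion in IMU stream", call. = FALSE)
  quat <- quat / qn
  out <- data.frame(time = time, ax = accel[, 1L], ay = accel[, 2L],
                    az = accel[, 3L], qw = quat[, 1L], qx = quat[, 2L],
                    qy = quat[, 3L], qz = quat[, 4L])
  structure(out, class = c("imu_stream", "data.frame"))
}

check_time <- function(time, n) {
  if (length(time) != n) stop("time length mismatch", call. = FALSE)
  if (anyNA(time)) stop("time contains NA", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  invisible(time)
}

#' Read a force-sensor log
#'
#' Reads a CSV with header `time,fx1,fy1,fz1,...,fx4,fy4,fz4` (seconds,
#' newtons, SI) and validates monotone time.
#'
#' @param path Path to the CSV file.
#' @return A [force_stream()].
#' @export
read_force_log <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", force_columns())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("force log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  force_stream(d$time, d[force_columns()])
}

#' Read an IMU log
#'
#' Reads a CSV with header `time,ax,ay,az,qw,qx,qy,qz`. Quaternions are
#' renormalized to unit norm; near-zero quaternions are rejected.
#'
#' @param path Path to the CSV file.
#' @return An [imu_stream()].
#' @export
read_imu_log <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", "ax", "ay", "az", "qw", "qx", "qy", "qz")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("IMU log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  imu_stream(d$time, as.matrix(d[c("ax", "ay", "az")]),
             as.matrix(d[c("qw", "qx", "qy", "qz")]))
}

#' Write force / IMU logs
#'
#' Inverse of [read_force_log()] / [read_imu_log()]; full double precision is
#' preserved (values written with 17 significant digits).
#'
#' @param stream A `force_stream` or `imu_stream`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(stream, path) {
  df <- as.data.frame(stream)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write session metadata
#'
#' Session metadata is stored as a flat YAML key-value file mirroring the
#' fields of [session_meta()].
#'
#' @param path YAML file path.
#' @return [read_session_meta()] returns a `session_meta`;
#'   [write_session_meta()] returns `path` invisibly.
#' @export
read_session_meta <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(session_meta, y)
}

#' @rdname read_session_meta
#' @param meta A `session_meta` object.
#' @export
write_session_meta <- function(meta, path) {
  yaml::write_yaml(unclass(meta), path, precision = 15L)
  invisible(path)
}

#' Interpolate an orientation trace onto the force-sensor clock
#'
#' The IMU supplies Euler angles on its own ~70 Hz clock while the rotation
#' of localized GRFs into the ground frame must be applied per force sample
#' (~400 Hz). Each angle channel is linearly interpolated; query times outside
#' the orientation span are clamped to the end values.
#'
#' @param orientation An `orientation_trace` (see
#'   [accumulate_orientation()]): data.frame `time, theta, phi, psi`, degrees.
#' @param force_time Numeric vector of force-clock sample times (seconds).
#' @return An `orientation_trace` on the force clock.
#' @export
interpolate_orientation_to_force_clock <- function(orientation, force_time) {
  if (nrow(orientation) == 0L || length(force_time) == 0L)
    stop("empty inputs", call. = FALSE)
  interp <- function(y) stats::approx(orientation$time, y, xout = force_time,
                                      rule = 2)$y
  orientation_trace(force_time,
                    theta = interp(orientation$theta),
                    phi   = interp(orientation$phi),
                    psi   = interp(orientation$psi))
}
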