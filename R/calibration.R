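#' Fit accelerometer gains and biases from stationary postures
#'
#' Estimates a six-parameter calibration model (per-axis gain and bias) from a
#' set of stationary acceleration readings taken in varied postures, by
#' requiring the calibrated acceleration norm to equal the gravitational
#' constant 9.81 m/s^2 in every posture. The residual for posture k is
#' `||gain * (a_k - bias)|| - 9.81` and the sum of squares is minimized by
#' damped Gauss-Newton (Levenberg-style) iteration starting from gain
#' (1,1,1), bias (0,0,0).
#'
#' @param postures n x 3 numeric matrix (n >= 6) of stationary acceleration
#'   triplets, m/s^2. Directions must span 3D space (at least 6 sufficiently
#'   distinct postures), otherwise the 6 parameters are not identifiable.
#' @param tol Convergence tolerance on the parameter-step norm. Default 1e-10.
#' @param max_iter Maximum number of iterations. Default 100.
#' @return A `calibration_model`: list with `gain` (3-vector, dimensionless),
#'   `bias` (3-vector, m/s^2), `g_ref` (9.81), `residual_rms` (m/s^2) and
#'   `objective_trace` (accepted objective values, non-increasing).
#' @export
fit_calibration <- function(postures, tol = 1e-10, max_iter = 100L) {
  postures <- as.matrix(postures)
  if (ncol(postures) != 3L) stop("postures must be n x 3", call. = FALSE)
  n <- nrow(postures)
  if (n < 6L) stop("need >= 6 postures to identify 6 parameters",
                   call. = FALSE)
  dirs <- postures / sqrt(rowSums(postures^2))
  if (qr(dirs)$rank < 3L)
    stop("degenerate postures: directions do not span 3D space",
         call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)

  g_ref <- 9.81
  p <- c(1, 1, 1, 0, 0, 0)  # (gain, bias)
  resid_fun <- function(p) {
    cal <- sweep(postures, 2L, p[4:6], "-")
    cal <- sweep(cal, 2L, p[1:3], "*")
    sqrt(rowSums(cal^2)) - g_ref
  }
  jac_fun <- function(p) {
    cal <- sweep(postures, 2L, p[4:6], "-")
    scl <- sweep(cal, 2L, p[1:3], "*")
    nrm <- sqrt(rowSums(scl^2))
    J <- matrix(0, n, 6L)
    for (j in 1:3) {
      # d||.||/d gain_j and d||.||/d bias_j
      J[, j] <- scl[, j] * cal[, j] / nrm
      J[, 3L + j] <- -scl[, j] * p[j] / nrm
    }
    J
  }

  r <- resid_fun(p)
  obj <- sum(r^2)
  trace <- obj
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- jac_fun(p)
    A <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (k in 1:30) {
      step <- tryCatch(solve(A + lambda * diag(diag(A) + 1e-12), -g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      p_new <- p + as.vector(step)
      r_new <- resid_fun(p_new)
      obj_new <- sum(r_new^2)
      if (is.finite(obj_new) && obj_new <= obj) {
        step_ok <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no improving step: at a minimum
    lambda <- max(lambda / 10, 1e-12)
    step_norm <- sqrt(sum((p_new - p)^2))
    p <- p_new; r <- r_new; obj <- obj_new
    trace <- c(trace, obj)
    if (step_norm < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(class = c("shoegait_convergence_error", "error",
                                "condition"),
                      list(message = "calibration did not converge",
                           call = sys.call(-1), last = p))
    stop(cond)
  }
  structure(list(gain = p[1:3], bias = p[4:6], g_ref = g_ref,
                 residual_rms = sqrt(obj / n), objective_trace = trace),
            class = "calibration_model")
}

#' Apply a calibration model to raw accelerations
#'
#' Elementwise `gain * (a - bias)` per axis.
#'
#' @param model A `calibration_model` from [fit_calibration()], or a list
#'   with `gain` and `bias` 3-vectors.
#' @param accel n x 3 matrix of raw accelerations, m/s^2.
#' @return n x 3 matrix of calibrated accelerations.
#' @export
apply_calibration <- function(model, accel) {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3L)
  out <- sweep(sweep(accel, 2L, model$bias, "-"), 2L, model$gain, "*")
  dimnames(out) <- dimnames(accel)
  out
}

#' Identity calibration model
#'
#' Convenience constructor: gains 1, biases 0 (raw readings passed through).
#' @return A `calibration_model`.
#' @export
identity_calibration <- function() {
  structure(list(gain = c(1, 1, 1), bias = c(0, 0, 0), g_ref = 9.81,
                 residual_rms = NA_real_, objective_trace = numeric()),
            class = "calibration_model")
}

#' Read / write a calibration model as YAML
#' @param path YAML file path.
#' @return [read_calibration()] returns a `calibration_model`.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(gain = as.numeric(y$gain), bias = as.numeric(y$bias),
                 g_ref = 9.81,
                 residual_rms = as.numeric(y$residual_rms %||% NA_real_),
                 objective_trace = numeric()),
            class = "calibration_model")
}

#' @rdname read_calibration
#' @param model A `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  yaml::write_yaml(list(gain = as.numeric(model$gain),
                        bias = as.numeric(model$bias),
                        residual_rms = as.numeric(model$residual_rms)),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
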