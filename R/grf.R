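#' Transform localized forces into the ground frame
#'
#' Rotates each sensor's shoe-local force triplet `(Fx'i, Fy'i, Fz'i)` into
#' the horizontal/vertical ground frame with `Ry(phi) Rx(theta)` per force
#' sample, using Euler angles interpolated onto the force clock.
#'
#' @param force A [force_stream()] (shoe-local frame).
#' @param angles An `orientation_trace` aligned to the force clock (same
#'   length as `force`); `psi` is ignored by this transform.
#' @return A `force_stream` in the ground frame (x lateral, y forward,
#'   z vertical).
#' @export
transform_to_ground <- function(force, angles) {
  if (nrow(angles) != nrow(force))
    stop("angles must be aligned to the force clock", call. = FALSE)
  th <- deg2rad(angles$theta); ph <- deg2rad(angles$phi)
  ct <- cos(th); st <- sin(th); cp <- cos(ph); sp <- sin(ph)
  out <- force
  for (i in 1:4) {
    fx <- force[[paste0("fx", i)]]
    fy <- force[[paste0("fy", i)]]
    fz <- force[[paste0("fz", i)]]
    # Ry(phi) Rx(theta) applied row-wise, expanded for vectorization
    y1 <- ct * fy - st * fz
    z1 <- st * fy + ct * fz
    out[[paste0("fx", i)]] <- cp * fx + sp * z1
    out[[paste0("fy", i)]] <- y1
    out[[paste0("fz", i)]] <- -sp * fx + cp * z1
  }
  out
}

total_vertical <- function(force) {
  force$fz1 + force$fz2 + force$fz3 + force$fz4
}

#' Detect stance phases from the summed vertical force
#'
#' A stance phase begins at the first sample where the summed vertical force
#' of the four sensors exceeds the threshold (15 N) and ends at the first
#' subsequent sample where it falls back below. Candidate phases shorter than
#' `min_stance` are discarded and phases separated by a swing shorter than
#' `min_swing` are merged, to suppress threshold chatter.
#'
#' @param grf A ground-frame [force_stream()].
#' @param threshold_n Onset/offset threshold in newtons. Default 15.
#' @param min_stance Minimum stance duration, s. Default 0.2.
#' @param min_swing Minimum swing separation, s. Default 0.1.
#' @return A data.frame with columns `start_idx`, `end_idx` (sample indices,
#'   stance = samples with total Fz above threshold) and `duration` (s).
#' @export
detect_stance_phases <- function(grf, threshold_n = 15, min_stance = 0.2,
                                 min_swing = 0.1) {
  if (nrow(grf) == 0L) stop("empty force signal", call. = FALSE)
  tot <- total_vertical(grf)
  above <- tot > threshold_n
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ph <- data.frame(start_idx = starts[r$values], end_idx = ends[r$values])
  if (nrow(ph) == 0L)
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      duration = numeric()))
  tme <- grf$time
  # merge phases separated by a too-short swing
  if (nrow(ph) > 1L) {
    keep <- ph[1L, , drop = FALSE]
    for (k in 2:nrow(ph)) {
      gap <- tme[ph$start_idx[k]] - tme[keep$end_idx[nrow(keep)]]
      if (gap < min_swing) {
        keep$end_idx[nrow(keep)] <- ph$end_idx[k]
      } else {
        keep <- rbind(keep, ph[k, ])
      }
    }
    ph <- keep
  }
  ph$duration <- tme[ph$end_idx] - tme[ph$start_idx]
  ph <- ph[ph$duration >= min_stance, , drop = FALSE]
  rownames(ph) <- NULL
  ph
}

#' Time-normalize one stance phase to 101 samples
#'
#' Each of the 12 ground-frame channels is linearly interpolated onto 101
#' equally spaced time points spanning the stance phase, 0% = heel contact to
#' 100% = toe off, and the per-sample total over the four sensors is added.
#'
#' @param grf A ground-frame [force_stream()].
#' @param phase One row of [detect_stance_phases()] output (or a list with
#'   `start_idx`, `end_idx`).
#' @return A `normalized_stance`: list with `values` (4 x 3 x 101 array,
#'   sensors x directions x percent samples, N), `total` (3 x 101 matrix) and
#'   `pct` (0:100).
#' @export
normalize_stance <- function(grf, phase) {
  i0 <- phase$start_idx[1L]; i1 <- phase$end_idx[1L]
  if (i0 < 1L || i1 > nrow(grf) || i1 - i0 < 2L)
    stop("stance phase too short or outside the signal", call. = FALSE)
  tt <- grf$time[i0:i1]
  tq <- seq(tt[1L], tt[length(tt)], length.out = 101L)
  values <- array(NA_real_, dim = c(4L, 3L, 101L),
                  dimnames = list(sensor = c("heel", "mt1", "mt5", "toe"),
                                  direction = c("x", "y", "z"),
                                  pct = 0:100))
  axes <- c("fx", "fy", "fz")
  for (i in 1:4) for (d in 1:3) {
    y <- grf[[paste0(axes[d], i)]][i0:i1]
    values[i, d, ] <- stats::approx(tt, y, xout = tq)$y
  }
  total <- apply(values, c(2L, 3L), sum)
  structure(list(values = values, total = total, pct = 0:100),
            class = "normalized_stance")
}

segment_bins <- function() {
  # ten 10% bins over the 1-100% samples; index 1 of the 101-grid is 0%
  lapply(1:10, function(k) seq(10L * (k - 1L) + 2L, 10L * k + 1L))
}

#' Per-segment summary of body-mass-normalized total GRF
#'
#' Averages the total ground-frame GRF, divided by body mass, within each of
#' ten 10% segments of the stance phase (1-10%, ..., 91-100%; the 0% heel
#' contact sample is excluded), then averages across stances.
#'
#' @param stances List of `normalized_stance` objects (>= 1).
#' @param body_mass Body mass, kg (> 0).
#' @return Data.frame `direction, segment, mean_n_per_kg` (30 rows).
#' @export
segment_summary <- function(stances, body_mass) {
  if (!length(stances)) stop("need at least one stance", call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be positive", call. = FALSE)
  bins <- segment_bins()
  per_stance <- lapply(stances, function(s) {
    vapply(bins, function(idx) rowMeans(s$total[, idx, drop = FALSE]),
           numeric(3L)) / body_mass   # 3 x 10
  })
  m <- Reduce(`+`, per_stance) / length(per_stance)
  data.frame(direction = rep(c("x", "y", "z"), times = 10L),
             segment = rep(1:10, each = 3L),
             mean_n_per_kg = as.vector(m))
}

#' Percentage contribution of each sensor per stance segment
#'
#' For each direction and 10% segment, the contribution of sensor i is
#' `100 * mean_i / mean_total` over the segment, using signed segment means.
#' Where the total's segment mean is within `eps` of zero (possible for the
#' shear directions, whose signed totals can vanish) the contribution is
#' undefined and returned as `NA`.
#'
#' @param stance A `normalized_stance`.
#' @param eps Denominator guard in newtons. Default 1.
#' @return Data.frame `sensor, direction, segment, contribution_pct`
#'   (4 x 3 x 10 rows).
#' @export
contribution_percent <- function(stance, eps = 1) {
  bins <- segment_bins()
  sensors <- c("heel", "mt1", "mt5", "toe")
  dirs <- c("x", "y", "z")
  out <- expand.grid(sensor = sensors, direction = dirs, segment = 1:10,
                     stringsAsFactors = FALSE)
  out$contribution_pct <- NA_real_
  for (k in 1:10) {
    idx <- bins[[k]]
    tot_mean <- rowMeans(stance$total[, idx, drop = FALSE])   # per direction
    for (d in 1:3) {
      if (abs(tot_mean[d]) < eps) next
      sens_mean <- rowMeans(stance$values[, d, idx])
      rows <- out$segment == k & out$direction == dirs[d]
      out$contribution_pct[rows] <- 100 * sens_mean / tot_mean[d]
    }
  }
  out
}
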