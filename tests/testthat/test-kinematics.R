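test_that("gravity cancels for a stationary IMU in any attitude", {
  withr::local_seed(51)
  n <- 200
  t <- seq(0, by = 1 / 70, length.out = n)
  for (ang in list(c(0, 0), c(20, -10), c(-35, 15))) {
    R <- rotation_global(ang[1], ang[2], 0)
    a_local <- as.numeric(crossprod(R, c(0, 0, 9.81)))
    imu <- imu_stream(t, matrix(rep(a_local, each = n), ncol = 3),
                      matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4))
    tr <- orientation_trace(t, rep(ang[1], n), rep(ang[2], n), rep(0, n))
    g <- to_global_accel(imu, tr, filter = "none")
    expect_lt(max(abs(g$accel)), 1e-9)
  }
})

test_that("band-pass removes DC and sub-gait drift, keeps gait band", {
  fs <- 70
  bp <- function(x) bandpass_accel(cbind(x, 0, 0), fs)[, 1]
  t <- seq(0, 30, by = 1 / fs)
  dc <- bp(rep(5, length(t)))
  expect_lt(max(abs(dc[500:1500])), 1e-6)
  expect_equal(sine_gain(bp, 5, fs), 1, tolerance = 0.02)
  g01 <- sine_gain(function(x) bp(x), 0.1, fs, n_cycles = 4)
  expect_lt(g01, 0.05)  # > 95 % attenuation at 0.1 Hz
  # upper corner is clipped below Nyquist: no error at fs = 70
  expect_silent(bandpass_accel(matrix(rnorm(300), ncol = 3), 70))
})

test_that("flat-foot detection separates rest from motion", {
  imu <- stationary_imu(300)
  g <- to_global_accel(imu, orientation_trace(imu$time, 0 * imu$time,
                                              0 * imu$time, 0 * imu$time),
                       filter = "none")
  mask <- detect_flat_foot(imu, g)
  expect_true(all(mask))
  # violent motion everywhere: no flat foot -> segmentation error
  imu2 <- imu
  imu2$ax <- 30 * sin(2 * pi * 3 * imu$time)
  g2 <- to_global_accel(imu2, orientation_trace(imu$time, 0 * imu$time,
                                                0 * imu$time, 0 * imu$time),
                        filter = "none")
  expect_error(detect_flat_foot(imu2, g2), "no flat-foot")
})

test_that("stride segmentation spans flat-foot midpoints", {
  n <- 400
  mask <- rep(FALSE, n)
  mask[90:110] <- TRUE    # run centered at 100
  mask[200:220] <- TRUE   # run centered at 210
  attr(mask, "runs") <- data.frame(start_idx = c(90L, 200L),
                                   end_idx = c(110L, 220L))
  st <- segment_strides(mask)
  expect_equal(nrow(st), 1L)
  expect_equal(st$start_idx, 100L)
  expect_equal(st$end_idx, 210L)
  expect_equal(st$swing_start_idx, 110L)
  expect_equal(st$swing_end_idx, 200L)
  # k + 1 runs give k strides
  runs <- data.frame(start_idx = seq(1, 601, by = 100),
                     end_idx = seq(21, 621, by = 100))
  mask2 <- rep(FALSE, 650)
  for (k in seq_len(nrow(runs))) mask2[runs$start_idx[k]:runs$end_idx[k]] <- TRUE
  attr(mask2, "runs") <- runs
  expect_equal(nrow(segment_strides(mask2)), nrow(runs) - 1L)
  attr(mask, "runs") <- runs[1, ]
  expect_error(segment_strides(mask), "two flat-foot")
})

test_that("ZUPT integration is exact for zero and constant-bias input", {
  n <- 120
  t <- seq(0, by = 1 / 70, length.out = n)
  strides <- data.frame(start_idx = 1L, end_idx = n,
                        swing_start_idx = 10L, swing_end_idx = n - 10L)
  zero <- structure(list(time = t, accel = matrix(0, n, 3)),
                    class = "global_accel")
  z <- integrate_with_zupt(zero, strides)[[1]]
  expect_true(all(z$velocity == 0))
  expect_true(all(z$position == 0))
  # constant bias b: uncorrected velocity is a ramp b*t, which the linear
  # drift model removes entirely; vertical displacement is pinned to zero
  bias <- c(0.4, -0.3, 0.25)
  biased <- structure(list(time = t,
                           accel = matrix(rep(bias, each = n), n, 3)),
                      class = "global_accel")
  zb <- integrate_with_zupt(biased, strides)[[1]]
  expect_equal(zb$velocity[n, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(zb$position[n, 3], 0, tolerance = 1e-12)
  expect_equal(zb$drift_velocity, bias * (t[n] - t[1]), tolerance = 1e-9)
  expect_lt(max(abs(zb$velocity)), 1e-9)
  expect_error(integrate_with_zupt(zero,
                                   data.frame(start_idx = 1L, end_idx = 3L,
                                              swing_start_idx = 1L,
                                              swing_end_idx = 3L)),
               "shorter")
})

test_that("stride length is the horizontal displacement norm", {
  expect_equal(stride_length(matrix(0, 10, 3)), 0)
  p <- matrix(0, 10, 3); p[10, 1] <- 1.2
  expect_equal(stride_length(p), 1.2)
  p[10, 2] <- 0.1
  expect_equal(stride_length(p), sqrt(1.2^2 + 0.1^2))
  expect_equal(stride_length(p), 1.2042, tolerance = 1e-4)
})

test_that("stride length is invariant under heading rotation", {
  withr::local_seed(61)
  traj <- cbind(cumsum(runif(50, 0, 0.05)), cumsum(runif(50, 0, 0.01)),
                rnorm(50, 0, 0.02))
  l0 <- stride_length(traj)
  for (ang in c(30, 117, 251)) {
    R <- shoegait:::rot_z(ang * pi / 180)
    expect_equal(stride_length(t(R %*% t(traj))), l0, tolerance = 1e-12)
  }
})

test_that("toe clearance adds the mounting height", {
  expect_equal(toe_clearance(rep(0, 5)), rep(0.03, 5))
  z <- c(0, 0.02, 0.05, 0.02, 0)
  expect_equal(max(toe_clearance(z)), 0.08)
  expect_equal(toe_clearance(z, initial_height = 0.01), z + 0.01)
})

test_that("minimum toe clearance picks the mid-swing dip", {
  t <- seq(0, 1, by = 0.005)
  swing <- c(0.2, 0.8)
  # double-hump curve with interior dip to 0.015 m at t = 0.5
  clr <- 0.015 + 0.06 * (sin(pi * (t - 0.2) / 0.6))^2 *
    (cos(2 * pi * (t - 0.5) / 0.6))^2
  clr[t < 0.2 | t > 0.8] <- 0.03
  expect_equal(minimum_toe_clearance(clr, t, swing), 0.015, tolerance = 1e-9)
  # monotone trace in the window: fallback to the window minimum
  mono <- 0.1 - 0.05 * t
  expect_equal(minimum_toe_clearance(mono, t, swing),
               min(mono[t >= 0.35 & t <= 0.65]), tolerance = 1e-12)
  expect_error(minimum_toe_clearance(clr, t, c(2, 3)), "empty")
})

test_that("noiseless simulated strides are recovered accurately", {
  ses <- simulate_session(default_profiles()$young, 6, seed = 71,
                          noise = no_noise())
  an <- analyze_session(ses, grf = FALSE)
  expect_equal(nrow(an$strides), 6L)
  rel <- abs(an$strides$stride_length_m - ses$truth$stride_length_m) /
    ses$truth$stride_length_m
  expect_lt(max(rel), 0.02)
  # MTC limited by 70 Hz trapezoid discretization of the fast vertical path
  expect_lt(sqrt(mean((an$strides$mtc_m - ses$truth$mtc_m)^2)), 0.005)
})

test_that("an older-adult stride's MTC is recovered within 0.005 m", {
  ses <- simulate_session(default_profiles()$older, 5, seed = 79,
                          noise = no_noise())
  an <- analyze_session(ses, grf = FALSE)
  expect_lt(max(abs(an$strides$mtc_m - ses$truth$mtc_m)), 0.005)
})

test_that("stride-length error shrinks as the IMU rate increases", {
  errs <- vapply(c(70, 140, 280), function(rate) {
    ses <- simulate_session(default_profiles()$young, 5, seed = 73,
                            noise = no_noise(), imu_rate = rate)
    an <- analyze_session(ses, grf = FALSE)
    sqrt(mean((an$strides$stride_length_m -
                 ses$truth$stride_length_m)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], 0.01)
})
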