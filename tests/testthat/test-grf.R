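test_that("the 50 Hz low-pass preserves DC and the passband, kills 150 Hz", {
  fs <- 400
  t <- seq(0, 2, by = 1 / fs)
  dc <- single_channel_force(t, rep(100, length(t)))
  out <- lowpass_forces(dc, fs)
  expect_equal(out$fz1, rep(100, length(t)), tolerance = 1e-9)
  # frequency response vs the analytic zero-phase Butterworth magnitude
  lp <- function(x) shoegait:::zero_phase(shoegait:::butter_lowpass(50, fs), x)
  g5 <- sine_gain(lp, 5, fs)
  expect_equal(g5, 1, tolerance = 0.01)
  g150 <- sine_gain(lp, 150, fs)
  expect_lt(g150, 0.03)  # > 97 % attenuation
  expect_equal(g150, butter_mag2(150, 50, fs, type = "low"),
               tolerance = 5e-3)
  expect_error(lowpass_forces(dc, fs = 90), "cutoff")
})

test_that("offsets are recovered from unloaded samples", {
  t <- seq(0, 1, by = 1 / 400)
  n <- length(t)
  swing <- t > 0.5
  withr::local_seed(13)
  offs <- rnorm(12, 0, 3)
  truth <- matrix(rnorm(n * 12), n, 12)
  truth[swing, ] <- 0
  fs <- force_stream(t, sweep(truth, 2, offs, "+"))
  out <- remove_offsets(fs, swing)
  for (j in seq_along(shoegait:::force_columns())) {
    ch <- shoegait:::force_columns()[j]
    expect_equal(out[[ch]][swing], truth[swing, j], tolerance = 1e-9)
  }
  # zero-offset input unchanged
  fs0 <- force_stream(t, truth)
  expect_equal(remove_offsets(fs0, swing)$fy2, truth[, 5], tolerance = 1e-12)
  expect_error(remove_offsets(fs, rep(FALSE, n)), "unloaded")
})

test_that("ground transform matches per-sample rotation and preserves norm", {
  t <- seq(0, 0.1, by = 1 / 400)
  n <- length(t)
  idt <- orientation_trace(t, rep(0, n), rep(0, n), rep(0, n))
  f <- force_stream(t, matrix(rnorm(n * 12), n, 12))
  expect_equal(transform_to_ground(f, idt), f, tolerance = 1e-14)
  # quarter turn about y sends +z' to +x
  q <- orientation_trace(t, rep(0, n), rep(90, n), rep(0, n))
  fz <- single_channel_force(t, rep(10, n), "fz1")
  out <- transform_to_ground(fz, q)
  expect_equal(out$fx1, rep(10, n), tolerance = 1e-12)
  expect_equal(out$fz1, rep(0, n), tolerance = 1e-12)
  # brute-force per-sample matrix product oracle with time-varying angles
  withr::local_seed(17)
  ang <- orientation_trace(t, runif(n, -30, 30), runif(n, -30, 30),
                           runif(n, -180, 180))
  out2 <- transform_to_ground(f, ang)
  for (k in sample(n, 10)) {
    R <- rotation_ground(ang$theta[k], ang$phi[k])
    for (i in 1:4) {
      vin <- c(f[[paste0("fx", i)]][k], f[[paste0("fy", i)]][k],
               f[[paste0("fz", i)]][k])
      vout <- c(out2[[paste0("fx", i)]][k], out2[[paste0("fy", i)]][k],
                out2[[paste0("fz", i)]][k])
      expect_equal(vout, as.numeric(R %*% vin), tolerance = 1e-12)
      expect_equal(sqrt(sum(vout^2)), sqrt(sum(vin^2)), tolerance = 1e-9)
    }
  }
})

test_that("stance detection finds 15 N threshold crossings", {
  fs <- 400
  t <- seq(0, 3, by = 1 / fs)
  n <- length(t)
  expect_equal(nrow(detect_stance_phases(single_channel_force(t,
                                                              rep(0, n)))), 0)
  # rectangular pulse: one phase spanning the pulse
  pulse <- ifelse(t >= 1 & t < 1.6, 600, 0)
  ph <- detect_stance_phases(single_channel_force(t, pulse))
  expect_equal(nrow(ph), 1L)
  expect_equal(t[ph$start_idx], 1, tolerance = 1.5 / fs)
  expect_equal(t[ph$end_idx], 1.6, tolerance = 1.5 / fs)
  # two-bump trace vs exhaustive linear-scan oracle
  bump <- function(c0, w) 400 * exp(-(t - c0)^2 / (2 * w^2))
  tot <- bump(0.8, 0.12) + bump(2.0, 0.12)
  f <- single_channel_force(t, tot)
  ph2 <- detect_stance_phases(f)
  expect_equal(nrow(ph2), 2L)
  above <- tot > 15
  oracle_starts <- which(diff(c(FALSE, above)) == 1)
  oracle_ends <- which(diff(c(above, FALSE)) == -1)
  expect_true(all(abs(ph2$start_idx - oracle_starts) <= 1))
  expect_true(all(abs(ph2$end_idx - oracle_ends) <= 1))
})

test_that("stance detection mirrors under time reversal", {
  fs <- 400
  t <- seq(0, 3, by = 1 / fs)
  tot <- 500 * exp(-(t - 1.1)^2 / 0.02) + 450 * exp(-(t - 2.2)^2 / 0.015)
  ph_f <- detect_stance_phases(single_channel_force(t, tot))
  ph_r <- detect_stance_phases(single_channel_force(t, rev(tot)))
  n <- length(t)
  expect_equal(sort(n + 1 - ph_r$end_idx), sort(ph_f$start_idx))
  expect_equal(sort(n + 1 - ph_r$start_idx), sort(ph_f$end_idx))
})

test_that("chattering crossings are debounced", {
  fs <- 400
  t <- seq(0, 2, by = 1 / fs)
  tot <- ifelse(t >= 0.5 & t < 1.2, 300, 0)
  tot[t >= 0.8 & t < 0.83] <- 5     # 30 ms dropout inside the stance
  tot[t >= 1.5 & t < 1.55] <- 100   # 50 ms blip (below min_stance)
  ph <- detect_stance_phases(single_channel_force(t, tot))
  expect_equal(nrow(ph), 1L)
  expect_equal(t[ph$start_idx], 0.5, tolerance = 2 / fs)
  expect_equal(t[ph$end_idx], 1.2, tolerance = 2 / fs)
})

test_that("stance normalization yields exactly 101 samples on the ramps", {
  fs <- 400
  t <- seq(0, 1, by = 1 / fs)
  n <- length(t)
  f <- single_channel_force(t, 3 + 7 * t)   # linear ramp channel
  phase <- data.frame(start_idx = 41L, end_idx = 361L)
  ns <- normalize_stance(f, phase)
  expect_equal(dim(ns$values), c(4L, 3L, 101L))
  expect_equal(dim(ns$total), c(3L, 101L))
  tq <- seq(t[41], t[361], length.out = 101)
  expect_equal(as.numeric(ns$values["heel", "z", ]), 3 + 7 * tq,
               tolerance = 1e-12)
  # endpoints equal the signal at the phase boundaries
  expect_equal(ns$values["heel", "z", 1], 3 + 7 * t[41], tolerance = 1e-12)
  expect_equal(ns$values["heel", "z", 101], 3 + 7 * t[361],
               tolerance = 1e-12)
  # dense-resample oracle on a rough random channel
  withr::local_seed(19)
  sig <- cumsum(rnorm(n))
  f2 <- single_channel_force(t, sig, "fy3")
  ns2 <- normalize_stance(f2, phase)
  oracle <- stats::approx(t[41:361], sig[41:361], xout = tq)$y
  expect_equal(as.numeric(ns2$values["mt5", "y", ]), oracle,
               tolerance = 1e-12)
  expect_error(normalize_stance(f, data.frame(start_idx = 5L, end_idx = 6L)),
               "too short")
})

test_that("segment summary averages body-mass-normalized totals per bin", {
  fs <- 400
  t <- seq(0, 1, by = 1 / fs)
  mass <- 70
  f <- single_channel_force(t, rep(mass * 9.81, length(t)))
  ph <- data.frame(start_idx = 1L, end_idx = length(t))
  ns <- normalize_stance(f, ph)
  seg <- segment_summary(list(ns), mass)
  expect_equal(nrow(seg), 30L)
  expect_equal(seg$mean_n_per_kg[seg$direction == "z"], rep(9.81, 10),
               tolerance = 1e-9)
  # linear total: bin means equal analytic averages over samples 2..11 etc.
  f2 <- single_channel_force(t, t * 100)
  ns2 <- normalize_stance(f2, ph)
  seg2 <- segment_summary(list(ns2), 1)
  pct_t <- seq(t[1], t[length(t)], length.out = 101)
  oracle <- vapply(1:10, function(k)
    mean(100 * pct_t[(10 * (k - 1) + 2):(10 * k + 1)]), numeric(1))
  expect_equal(seg2$mean_n_per_kg[seg2$direction == "z"], oracle,
               tolerance = 1e-9)
  # averaging two identical stances changes nothing
  seg3 <- segment_summary(list(ns2, ns2), 1)
  expect_equal(seg3, seg2, tolerance = 1e-12)
  expect_error(segment_summary(list(ns), 0), "positive")
})

test_that("contribution percentages are ratios summing to 100", {
  fs <- 400
  t <- seq(0, 1, by = 1 / fs)
  ph <- data.frame(start_idx = 1L, end_idx = length(t))
  # heel-only loading
  f <- single_channel_force(t, rep(500, length(t)), "fz1")
  cp <- contribution_percent(normalize_stance(f, ph))
  z <- cp[cp$direction == "z", ]
  expect_equal(z$contribution_pct[z$sensor == "heel"], rep(100, 10))
  expect_equal(z$contribution_pct[z$sensor == "toe"], rep(0, 10))
  # two equal sensors split 50/50
  f2 <- f; f2$fz4 <- f2$fz1
  cp2 <- contribution_percent(normalize_stance(f2, ph))
  z2 <- cp2[cp2$direction == "z" & cp2$sensor %in% c("heel", "toe"), ]
  expect_equal(z2$contribution_pct, rep(50, 20))
  # random loading: sums 100, matches the direct ratio oracle
  withr::local_seed(23)
  f3 <- force_stream(t, matrix(abs(rnorm(length(t) * 12, 50, 10)),
                               length(t), 12))
  ns3 <- normalize_stance(f3, ph)
  cp3 <- contribution_percent(ns3)
  for (d in c("x", "y", "z")) for (k in 1:10) {
    v <- cp3$contribution_pct[cp3$direction == d & cp3$segment == k]
    if (all(is.finite(v))) expect_equal(sum(v), 100, tolerance = 1e-9)
  }
  idx <- (10 * 2 + 2):(10 * 3 + 1)  # segment 3 oracle
  oracle <- 100 * mean(ns3$values["mt1", "y", idx]) /
    mean(ns3$total["y", idx])
  expect_equal(cp3$contribution_pct[cp3$sensor == "mt1" &
                                      cp3$direction == "y" &
                                      cp3$segment == 3], oracle,
               tolerance = 1e-9)
  # near-zero totals are undefined, not divided
  f4 <- single_channel_force(t, rep(0.1, length(t)), "fx1")
  cp4 <- contribution_percent(normalize_stance(f4, ph))
  expect_true(all(is.na(cp4$contribution_pct[cp4$direction == "x"])))
})
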