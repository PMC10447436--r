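test_that("dff uses a per-presentation 7-frame baseline at 15 Hz", {
  fs <- 15
  row <- list(t_on_s = 2, t_off_s = 7)
  # constant baseline 100, stimulus frames at 150 -> dff constant 0.5
  n <- 10 * fs
  t <- (seq_len(n) - 1) / fs
  v <- rep(100, n); v[t >= 2 & t < 7] <- 150
  tr <- sweep_trace(v, fs, 2, 7, channel_kind = "fluorescence")
  d <- dff(tr, row)
  expect_equal(as.numeric(d), rep(0.5, sum(t >= 2 & t < 7)))
  # F identical to F0 -> 0
  flat <- sweep_trace(rep(100, n), fs, 2, 7, channel_kind = "fluorescence")
  expect_equal(max(abs(dff(flat, row))), 0)
  # ramp baseline: F0 = mean of exactly the floor(0.5 * 15) = 7 frames
  # immediately before onset
  vr <- as.numeric(seq_len(n))          # frame index as brightness
  trr <- sweep_trace(vr, fs, 2, 7, channel_kind = "fluorescence")
  i_on <- which(t >= 2)[1]
  f0_expected <- mean(vr[(i_on - 7):(i_on - 1)])
  expect_equal(attr(dff(trr, row), "f0"), f0_expected)
  # F0 <= 0 is an invalid baseline
  neg <- sweep_trace(c(rep(-1, 50), rep(5, 100)), fs, 50 / fs, 120 / fs,
                     channel_kind = "fluorescence")
  expect_error(dff(neg, list(t_on_s = 50 / fs, t_off_s = 120 / fs)), "baseline")
})

test_that("time-averaged response honors its window", {
  fs <- 15
  const <- structure(rep(0.5, 75), frame_rate_hz = fs)
  expect_equal(time_avg_response(const, "full"), 0.5)
  expect_equal(time_avg_response(const, "avg_5s"), 0.5)
  # linear ramp 0 -> 1 over 5 s, full window -> mean 0.5
  ramp <- structure(seq(0, 1, length.out = 75), frame_rate_hz = fs)
  expect_equal(time_avg_response(ramp, "full"), 0.5)
  # delayed-onset response averages lower over the first 2 s than over 5 s
  expect_lt(time_avg_response(ramp, "first_2s"), time_avg_response(ramp, "avg_5s"))
  short <- structure(rep(0.5, 10), frame_rate_hz = fs)
  expect_error(time_avg_response(short, "avg_5s"), "window")
})

test_that("ROI responsiveness is a strict threshold count", {
  r <- rep(0.1, 24); r[1:4] <- 0.5
  expect_true(roi_responsive(r, threshold = 0.4, min_count = 3))
  r2 <- rep(0.1, 24); r2[1:2] <- 0.5
  expect_false(roi_responsive(r2, threshold = 0.4, min_count = 3))
  # responses exactly at threshold are not counted ('surpassed' is strict)
  r3 <- rep(0.4, 24)
  expect_false(roi_responsive(r3, threshold = 0.4, min_count = 3))
  expect_warning(roi_responsive(r, threshold = 0.9, min_count = 3), "band")
})

test_that("responsiveness is monotone in threshold and count", {
  set.seed(21)
  for (k in 1:20) {
    r <- runif(24, 0, 1)
    a <- roi_responsive(r, threshold = 0.4, min_count = 3)
    expect_true(!roi_responsive(r, threshold = 0.55, min_count = 3) || a)
    expect_true(!roi_responsive(r, threshold = 0.4, min_count = 6) || a)
  }
})

test_that("DSI/OSI match the closed-form circular harmonic sums", {
  dirs <- seq(0, 315, by = 45)
  # equal responses in all directions -> both indices 0
  t0 <- dsi_osi(rep(2, 8), dirs)
  expect_equal(t0$dsi, 0)
  expect_equal(t0$osi, 0)
  expect_false(t0$is_ds || t0$is_os)
  # all response in one direction -> both 1, preferred = that direction
  r1 <- numeric(8); r1[4] <- 1
  t1 <- dsi_osi(r1, dirs)
  expect_equal(t1$dsi, 1)
  expect_equal(t1$osi, 1)
  expect_equal(t1$pref_direction_deg, 135)
  # R(theta) = 1 + cos(theta - 90): DSI = 0.5 exactly, OSI = 0, pref 90
  r2 <- 1 + cos((dirs - 90) * pi / 180)
  t2 <- dsi_osi(r2, dirs)
  expect_equal(t2$dsi, 0.5)
  expect_equal(t2$osi, 0, tolerance = 1e-12)
  expect_equal(t2$pref_direction_deg, 90)
  # independent oracle: explicit complex sums
  v1 <- sum(r2 * exp(1i * dirs * pi / 180))
  expect_equal(t2$dsi, Mod(v1) / sum(r2))
  # all-zero responses -> undefined tuning
  tz <- dsi_osi(numeric(8), dirs)
  expect_true(is.na(tz$dsi) && !tz$is_ds && !tz$is_os)
})

test_that("selectivity indices are scale invariant and OSI is DSI at doubled angles", {
  dirs <- seq(0, 315, by = 45)
  set.seed(5)
  for (k in 1:15) {
    r <- runif(8, 0, 3)
    a <- dsi_osi(r, dirs)
    b <- dsi_osi(3.7 * r, dirs)
    expect_equal(a$dsi, b$dsi)
    expect_equal(a$osi, b$osi)
    expect_equal(a$pref_direction_deg, b$pref_direction_deg)
    # harmonic identity: OSI(pattern) = DSI of the same pattern at 2 theta
    doubled <- Mod(sum(r * exp(1i * (2 * dirs) * pi / 180))) / sum(r)
    expect_equal(a$osi, doubled)
  }
})

test_that("negative responses are clipped before the vector sums", {
  dirs <- seq(0, 315, by = 45)
  r <- c(-1, 0, 2, 0, -1, 0, 2, 0)
  tun <- dsi_osi(r, dirs)
  expect_true(tun$clipped)
  expect_true(tun$dsi >= 0 && tun$dsi <= 1 && tun$osi >= 0 && tun$osi <= 1)
  expect_equal(tun$responses, pmax(r, 0))
})

test_that("area-response summary reports argmax and end/max ratio", {
  r <- stats::setNames(c(1, 2, 4, 3, 1), c(100, 200, 300, 500, 900))
  ar <- area_response(r)
  expect_equal(ar$optimal_diameter_um, 300)
  expect_equal(ar$suppression_index, 0.25)
  rising <- stats::setNames(c(1, 2, 3), c(100, 200, 400))
  ar2 <- area_response(rising)
  expect_equal(ar2$suppression_index, 1.0)
  expect_equal(ar2$optimal_diameter_um, 400)
  expect_error(area_response(stats::setNames(c(0, 0, 0), c(1, 2, 3))), "degenerate")
})

test_that("circular mean handles wraparound and axial data", {
  # directions 10 and 350 average to 0, not 180
  cm <- circular_mean(c(10, 350))
  expect_equal(cm$mean_deg, 0, tolerance = 1e-9)
  # axial (orientation) data: 10 and 170 deg axes average to 0 (mod 180)
  co <- circular_mean(c(10, 170), orientation = TRUE)
  expect_equal(co$mean_deg, 0, tolerance = 1e-9)
  # concentrated sample: mean near the true center, small sem
  set.seed(3)
  a <- rnorm(50, 56, 5)
  co2 <- circular_mean(a, orientation = TRUE)
  expect_equal(co2$mean_deg, 56, tolerance = 0.05)
  expect_lt(co2$sem_deg, 2)
})

test_that("classification summary applies inclusion-exclusion", {
  cls <- classification_summary(206, 157, 15, 245)
  get <- function(w, col) cls[[col]][cls$class == w]
  expect_equal(get("both", "count"), 133)   # 206 + 157 - (245 - 15)
  expect_equal(get("os", "pct_rounded"), 84)
  expect_equal(get("neither", "pct_rounded"), 6)
  expect_equal(get("both", "pct_rounded"), 54)
  expect_equal(get("ds", "pct"), 100 * 157 / 245)
})

test_that("FOV summary counts classes and averages preferred angles", {
  mk <- function(dsi, osi, dir, ori) {
    structure(list(dsi = dsi, osi = osi, pref_direction_deg = dir,
                   pref_orientation_deg = ori,
                   is_ds = dsi >= 0.2, is_os = osi >= 0.2),
              class = "direction_tuning")
  }
  tunings <- c(lapply(1:6, function(i) mk(0.5, 0.5, 200, 55)),
               lapply(1:2, function(i) mk(0.05, 0.5, 10, 57)),
               list(mk(0.05, 0.05, 0, 0)))
  fs <- fov_summary(tunings)
  cls <- fs$classification
  expect_equal(cls$count[cls$class == "os"], 8)
  expect_equal(cls$count[cls$class == "ds"], 6)
  expect_equal(cls$count[cls$class == "both"], 6)
  expect_equal(cls$count[cls$class == "neither"], 1)
  expect_equal(fs$pref_direction$mean_deg, 200)
  expect_equal(fs$pref_orientation$mean_deg, 55.5, tolerance = 0.01)
  expect_equal(sum(fs$ori_hist), 8)
  # all untuned -> everything in 'neither'
  none <- fov_summary(list(mk(0.01, 0.01, 0, 0)))
  expect_equal(none$classification$count[none$classification$class == "neither"], 1)
  expect_equal(none$classification$count[none$classification$class == "os"], 0)
})
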