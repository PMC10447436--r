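test_that("charge transfer integrates baseline-subtracted current", {
  # constant 10 pA above a flat zero baseline for 5 s -> 50 pC
  tr <- flat_step_trace(baseline_pA = 0, step_pA = 10)
  expect_equal(charge_transfer(tr), 50)
  # nonzero DC offset is removed by baseline subtraction
  tr2 <- flat_step_trace(baseline_pA = -30, step_pA = 10)
  expect_equal(charge_transfer(tr2), 50)
  # trace identical to its baseline -> 0 pC
  tr3 <- flat_step_trace(step_pA = 0)
  expect_equal(charge_transfer(tr3), 0)
  # ramp 0 -> 10 pA over 5 s, zero baseline -> triangle area 25 pC
  fs <- 1000
  n <- round(6 * fs) + 1
  t <- (seq_len(n) - 1) / fs
  v <- ifelse(t >= 0.5 & t <= 5.5, 10 * (t - 0.5) / 5, 0)
  ramp <- sweep_trace(v, fs, 0.5, 5.5, holding_mV = 20)
  expect_equal(charge_transfer(ramp), 25)
})

test_that("charge transfer is additive over adjoining response windows", {
  set.seed(42)
  fs <- 2000
  v <- cumsum(rnorm(round(6 * fs) + 1, 0, 0.5))
  tr <- sweep_trace(v, fs, 0.5, 5.5, holding_mV = 20)
  whole <- charge_transfer(tr, response_window_s = c(0.5, 5.5))
  first <- charge_transfer(tr, response_window_s = c(0.5, 3))
  second <- charge_transfer(tr, response_window_s = c(3, 5.5))
  expect_equal(first + second, whole, tolerance = 1e-10)
})

test_that("charge transfer rejects bad inputs", {
  tr <- flat_step_trace()
  expect_error(charge_transfer(tr, response_window_s = c(0.5, 99)), "window")
  fluo <- sweep_trace(rep(100, 90), 15, 1, 5, channel_kind = "fluorescence")
  expect_error(charge_transfer(fluo), "current")
})

test_that("spike counting uses a half-open window", {
  tr <- spike_train(c(1.0, 2.0, 4.9), 6)
  expect_equal(spike_count(tr, c(0, 5)), 3)
  # spike exactly at the window end is excluded
  tr2 <- spike_train(c(1.0, 5.0), 6)
  expect_equal(spike_count(tr2, c(0, 5)), 1)
  expect_equal(spike_count(spike_train(numeric(0), 6), c(0, 5)), 0)
  expect_error(spike_count(tr, c(5, 1)), "inverted")
})

test_that("build_tuning_curve sorts, averages and flags single trials", {
  tc <- build_tuning_curve(list(`300` = c(5, 5, 5), `150` = c(10, 12, 14)),
                           units = "spikes")
  expect_equal(tc$x, c(150, 300))                      # sorted ascending
  expect_equal(tc$mean, c(12, 5))
  expect_equal(tc$sem, c(sd(c(10, 12, 14)) / sqrt(3), 0))
  expect_equal(tc$sem[1], 1.1547, tolerance = 1e-4)
  expect_equal(tc$normalization, "raw")
  # one trial per speed -> sem 0
  tc1 <- build_tuning_curve(list(`150` = 10, `300` = 5))
  expect_equal(tc1$sem, c(0, 0))
  expect_error(build_tuning_curve(list(`150` = c(1, 2))), "insufficient")
})

test_that("optimal speed takes the argmax with slow-tie convention", {
  tc <- curve_from_means(c(76, 150, 300), c(0.2, 1.0, 0.6))
  expect_equal(optimal_speed(tc), 150)
  plateau <- curve_from_means(c(76, 150, 300), c(1.0, 1.0, 0.5))
  expect_equal(optimal_speed(plateau), 76)
  expect_warning(zero <- optimal_speed(curve_from_means(c(76, 150), c(0, 0))),
                 "degenerate")
  expect_equal(zero, 76)
})

test_that("half-maximum speed interpolates the descending branch", {
  tc <- curve_from_means(c(76, 150, 300, 600), c(0.5, 1.0, 0.5, 0.25))
  expect_equal(half_max_speed(tc), 300)     # exact grid hit
  # hand interpolation: 150 + 150 * (1.0 - 0.5) / (1.0 - 0.4) = 275
  tc2 <- curve_from_means(c(150, 300), c(1.0, 0.4))
  expect_equal(half_max_speed(tc2), 275)
  # monotone rising curve -> cutoff beyond tested range
  rising <- curve_from_means(c(76, 150, 300), c(0.2, 0.5, 1.0))
  expect_true(is.infinite(half_max_speed(rising)))
})

test_that("half-maximum speed is invariant under normalization", {
  set.seed(7)
  for (k in 1:10) {
    m <- abs(rnorm(6, 5, 3)) + 0.1
    tc <- curve_from_means(c(76, 150, 300, 600, 1200, 2400), m)
    expect_equal(half_max_speed(normalize_curve(tc, "self_max")),
                 half_max_speed(tc))
  }
})

test_that("normalization scales by the right maximum", {
  tc <- curve_from_means(c(1, 2, 3), c(2, 4, 1))
  n1 <- normalize_curve(tc, "self_max")
  expect_equal(n1$mean, c(0.5, 1, 0.25))
  expect_equal(max(n1$mean), 1)
  expect_equal(n1$normalization, "self_max")
  # control_max: treated curve scaled by the control maximum
  ctrl <- curve_from_means(c(1, 2), c(3, 4))
  trt <- curve_from_means(c(1, 2), c(1, 2))
  n2 <- normalize_curve(trt, "control_max", reference = ctrl)
  expect_equal(n2$mean, c(0.25, 0.5))
  # idempotent under self_max
  expect_equal(normalize_curve(n1, "self_max")$mean, n1$mean)
  expect_error(normalize_curve(trt, "control_max"), "reference")
  expect_error(normalize_curve(curve_from_means(c(1, 2), c(0, 0)), "self_max"),
               "zero")
})

test_that("population average interpolates onto the union grid", {
  a <- curve_from_means(c(100, 400), c(0, 1))
  b <- curve_from_means(c(100, 200, 400), c(0, 0.5, 1))
  pop <- population_average(list(a, b))
  expect_equal(pop$x, c(100, 200, 400))
  # cell A interpolates to 1/3 at 200; mean = (1/3 + 0.5) / 2 = 5/12
  expect_equal(pop$mean[2], 5 / 12)
  expect_true(pop$measured_mask[2])   # B measured there
  # N copies of one curve reproduce it with sem 0
  pop2 <- population_average(list(b, b, b))
  expect_equal(pop2$mean, b$mean)
  expect_equal(pop2$sem, rep(0, 3))
  # disjoint ranges are an error
  c1 <- curve_from_means(c(10, 20), c(1, 2))
  c2 <- curve_from_means(c(100, 200), c(1, 2))
  expect_error(population_average(list(c1, c2)), "overlap")
})

test_that("speed-range shift is the difference of half crossings", {
  # control crosses 0.5 at 400, treated at 1900 -> shift 1500
  ctrl <- normalize_curve(curve_from_means(c(200, 400, 600), c(1, 0.5, 0.2)),
                          "self_max")
  trt0 <- curve_from_means(c(200, 1800, 2000), c(1, 0.55, 0.45))
  trt <- normalize_curve(trt0, "control_max", reference = trt0)
  expect_equal(speed_range_shift(ctrl, trt), 1500)
  expect_equal(speed_range_shift(ctrl, ctrl), 0)
  # treated crossing slower than control -> negative shift allowed
  slower <- normalize_curve(curve_from_means(c(200, 300, 600), c(1, 0.5, 0.2)),
                            "self_max")
  expect_equal(speed_range_shift(ctrl, slower), -100)
  expect_error(speed_range_shift(curve_from_means(c(1, 2), c(1, 2)), ctrl),
               "normalized")
})

test_that("E/I ratio masks low-inhibition points and rejects normalized input", {
  exc <- curve_from_means(c(100, 200), c(100, 100))
  inh <- curve_from_means(c(100, 200), c(100, 400))
  r <- ei_ratio(exc, inh)
  expect_equal(r$mean, c(1.0, 0.25))
  inh0 <- curve_from_means(c(100, 200), c(100, 0))
  r0 <- ei_ratio(exc, inh0)
  expect_true(is.na(r0$mean[2]))
  expect_false(r0$measured_mask[2])
  expect_error(ei_ratio(normalize_curve(exc, "self_max"), inh), "raw")
  bad_units <- curve_from_means(c(100, 200), c(1, 2), units = "spikes")
  expect_error(ei_ratio(exc, bad_units), "mismatch")
})

test_that("log-domain parabolic fit recovers a log-Gaussian peak exactly", {
  x <- c(76, 150, 300, 600, 1200, 2400)
  m <- 490 * exp(-(log(x) - log(710))^2 / (2 * 0.995^2))
  fit <- tuning_peak_fit(curve_from_means(x, m))
  expect_equal(fit$peak_x, 710, tolerance = 1e-6)
  expect_equal(fit$log_width, 0.995, tolerance = 1e-6)
})
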