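test_that("simulators are deterministic under a fixed seed", {
  p <- sim_params(seed = 42)
  a <- simulate_speed_series(p, c(150, 600), "inh_current")
  b <- simulate_speed_series(p, c(150, 600), "inh_current")
  expect_identical(a, b)
  expect_identical(simulate_opto_trial(p, 1, 20, "pr_block"),
                   simulate_opto_trial(p, 1, 20, "pr_block"))
  stims <- grating_stims()[1:2]
  expect_identical(simulate_roi_traces(p, stims, 2),
                   simulate_roi_traces(p, stims, 2))
  expect_identical(simulate_synapse_table(c(SAC = 10), seed = 3),
                   simulate_synapse_table(c(SAC = 10), seed = 3))
  # a different seed changes the draws
  expect_false(identical(a, simulate_speed_series(p, c(150, 600), "inh_current",
                                                  seed = 43)))
})

test_that("noiseless excitatory charge equals the amplitude at the peak speed", {
  p <- noiseless_params()
  speeds <- c(150, 300, 710, 1200, 2400)
  series <- simulate_speed_series(p, speeds, "exc_current", n_trials = 1)
  tc <- speed_tuning_from_series(series)
  at_peak <- tc$mean[tc$x == 710]
  expect_equal(at_peak, p$exc_amp_pC, tolerance = 1e-3)
  expect_true(all(tc$mean[tc$x != 710] < at_peak))
  # excitatory sweeps are inward (negative) at -65 mV; sign preserved by
  # charge_transfer, magnitude used for tuning
  expect_lt(charge_transfer(series[[3]]$trials[[1]]), 0)
})

test_that("combined glycine and GABA blockade abolishes evoked inhibition", {
  p <- sim_params(seed = 9)
  series <- simulate_speed_series(p, c(600, 1200), "inh_current",
                                  condition = "both")
  for (sp in series) for (tr in sp$trials) {
    # evoked charge is pure integrated noise: far below the control scale
    expect_lt(abs(charge_transfer(tr)), 0.02 * p$inh_amp_pC)
  }
})

test_that("pipeline half-max on the noiseless spike curve matches the analytic value", {
  p <- sim_params()
  speeds <- exp(seq(log(60), log(3000), length.out = 120))
  # noiseless spike tuning = the generator's expected counts
  counts <- ephys_mean_response(p, speeds, "spikes")
  tc <- curve_from_means(speeds, counts, units = "spikes")
  got <- half_max_speed(tc)
  # independent oracle: root-find the rectified E-I drive written out here
  drive <- function(v) {
    E <- p$exc_amp_pC * exp(-(log(v) - log(p$exc_peak_speed))^2 / (2 * p$exc_log_width^2))
    I <- p$inh_amp_pC * exp(-(log(v) - log(p$inh_peak_speed))^2 / (2 * p$inh_log_width^2))
    p$spike_gain * max(0, E - p$ei_weight * I)
  }
  vs <- seq(60, 3000, by = 1)
  vmax <- vs[which.max(vapply(vs, drive, 0))]
  half <- drive(vmax) / 2
  analytic <- uniroot(function(v) drive(v) - half, c(vmax, 3000))$root
  step <- speeds[which(speeds > analytic)[1]] / speeds[which(speeds > analytic)[1] - 1]
  expect_lt(abs(log(got / analytic)), log(step) + 1e-9)   # within one grid step
})

test_that("calibrated optima are recovered on the default grid", {
  p <- noiseless_params()
  targets <- c(spikes = 150, exc_current = 710, inh_current = 1220)
  grid <- default_speed_grid()
  for (mod in names(targets)) {
    tc <- if (mod == "spikes") {
      curve_from_means(grid, ephys_mean_response(p, grid, "spikes"), "spikes")
    } else {
      speed_tuning_from_series(
        simulate_speed_series(p, grid, mod, n_trials = 1))
    }
    got <- optimal_speed(tc)
    k <- which.min(abs(log(grid) - log(targets[[mod]])))
    expect_true(got %in% grid[max(1, k - 1):min(length(grid), k + 1)],
                info = mod)
  }
})

test_that("condition scaling follows the additive component partition", {
  p <- sim_params()
  v <- c(300, 700, 1200, 2400)
  ctrl <- ephys_mean_response(p, v, "inh_current", "control")
  stry <- ephys_mean_response(p, v, "inh_current", "strychnine")
  gaba <- ephys_mean_response(p, v, "inh_current", "gabazine")
  both <- ephys_mean_response(p, v, "inh_current", "both")
  cno <- ephys_mean_response(p, v, "inh_current", "cno")
  expect_equal(stry + gaba, ctrl + both)
  expect_equal(stry / ctrl, rep(1 - p$glycine_frac, 4))
  expect_equal(cno / ctrl, rep(1 - p$vglut3_frac_of_glycine * p$glycine_frac, 4))
  expect_equal(both, rep(0, 4))
  expect_error(simulate_speed_series(p, c(-5, 100), "spikes"), "positive")
  expect_error(ephys_mean_response(p, 100, "spikes", "unknown_drug"), "condition")
})

test_that("opto pulse peaks scale with duration and condition", {
  p <- noiseless_params()
  pk <- function(dur, hold, cond) {
    tr <- smooth_trace(simulate_opto_trial(p, dur, hold, cond, seed = 1))
    peak_evoked_current(tr)$peak_pA
  }
  expect_equal(pk(1, 20, "pr_block"), 43, tolerance = 0.01)
  # the 10 ms smoothing shaves a fraction of a pA off the transient peak
  expect_equal(pk(0.1, 20, "pr_block"), 26, tolerance = 0.02)
  expect_equal(pk(1, -65, "pr_block"), 9, tolerance = 0.01)
  # glutamate blockade removes the disynaptic IPSC fraction and the EPSC
  expect_equal(pk(1, 20, "glut_block") / pk(1, 20, "pr_block"),
               1 - p$opto_disyn_frac, tolerance = 0.01)
  expect_equal(pk(1, -65, "glut_block"), 0, tolerance = 1e-6)
  expect_equal(pk(1, 20, "all_block"), 0, tolerance = 1e-6)
  expect_error(simulate_opto_trial(p, -1, 20, "pr_block"), "pulse")
})

test_that("untuned ROI generator yields near-zero selectivity", {
  p <- noiseless_params(ca_dsi = 0, ca_osi = 0, seed = 2)
  rts <- simulate_roi_traces(p, grating_stims(), n_rois = 3, n_trials = 1)
  tun <- roi_direction_tuning(rts)
  for (t in tun) {
    expect_lt(t$dsi, 0.01)
    expect_lt(t$osi, 0.01)
  }
})

test_that("noiseless cosine-tuned ROI recovers DSI 0.5", {
  # pure first-harmonic tuning R = 1 + cos(theta - pref): DSI is 0.5 exactly
  p <- noiseless_params(ca_dsi = 0.5, ca_osi = 0, pref_direction_deg = 90,
                        seed = 4)
  rts <- simulate_roi_traces(p, grating_stims(), n_rois = 1, n_trials = 1)
  tun <- roi_direction_tuning(rts)[[1]]
  # the decaying tail of the previous presentation perturbs the next
  # baseline by ~exp(-interstim/decay tau), a few parts in a thousand
  expect_equal(tun$dsi, 0.5, tolerance = 5e-3)
  expect_lt(tun$osi, 5e-3)
  expect_equal(tun$pref_direction_deg, 90, tolerance = 0.5)
})

test_that("zero surround weight gives a monotone area-response curve", {
  p <- noiseless_params(surround_weight = c(spot = 0, grating = 0), seed = 6)
  diams <- c(50, 120, 220, 330, 470, 936)
  stims <- lapply(diams, function(d)
    stimulus_spec("spot", speed_um_s = 0, diameter_um = d, duration_s = 5))
  rts <- simulate_roi_traces(p, stims, n_rois = 1, n_trials = 1)
  resp <- roi_responses(rts, window = "first_2s")
  r <- stats::setNames(resp$response, resp$diameter_um)
  # nondecreasing up to inter-presentation crosstalk of a few parts in 1e3
  expect_true(all(diff(r[order(as.numeric(names(r)))]) >= -1e-3 * max(r)))
  ar <- area_response(r)
  expect_equal(ar$suppression_index, 1, tolerance = 1e-3)
})

test_that("mixed acquisition frame rates are rejected", {
  p <- sim_params()
  s <- grating_stims()[1:2]
  attr(s[[2]], "frame_rate_hz") <- 30
  expect_error(simulate_roi_traces(p, s, 2), "inconsistent")
})

test_that("synapse table generation honors requested counts and geometry", {
  tab <- simulate_synapse_table(reference_synapse_counts(), seed = 1)
  expect_equal(nrow(tab), 460)
  expect_equal(sum(tab$presyn_type == "VGluT3"), 40)
  expect_equal(length(unique(tab$presyn_cell_id[tab$presyn_type == "VGluT3"])), 16)
  expect_true(all(!duplicated(tab$synapse_id)))
  # empty counts -> empty table; tallies error downstream
  empty <- simulate_synapse_table(c(SAC = 0), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(tally_by_type(empty), "empty")
})

test_that("tilted geometry moves raw depths but not normalized ones", {
  geom <- band_geometry(tilt_x = 0.2, tilt_y = -0.1)
  tab <- simulate_synapse_table(c(SAC = 120), geom,
                                depth_centers = c(SAC = 1), depth_sds = c(SAC = 0),
                                seed = 8)
  # raw depth varies strongly with position under the tilt
  expect_gt(diff(range(tab$z_um)), 10)
  tab <- normalize_depth(tab, band_model_from_geometry(geom))
  expect_equal(tab$depth_norm, rep(1, 120), tolerance = 1e-9)
})

test_that("population-mean selectivity matches the generator targets", {
  p <- sim_params()
  tun <- list()
  for (f in 1:3) {
    rts <- simulate_roi_traces(p, grating_stims(), 40, seed = 500 + f)
    tun <- c(tun, roi_direction_tuning(rts))
  }
  expect_gte(length(tun), 100)
  expect_equal(mean(vapply(tun, function(t) t$dsi, 0)), p$ca_dsi,
               tolerance = 0.05 / p$ca_dsi)
  expect_equal(mean(vapply(tun, function(t) t$osi, 0)), p$ca_osi,
               tolerance = 0.05 / p$ca_osi)
  # a realistic minority of ROIs misses the 0.2 criterion
  frac_os <- mean(vapply(tun, function(t) t$is_os, TRUE))
  frac_ds <- mean(vapply(tun, function(t) t$is_ds, TRUE))
  expect_true(frac_os > 0.7 && frac_os < 0.95)
  expect_true(frac_ds > 0.5 && frac_ds < 0.85)
})

test_that("generator tuning peaks are recovered without bias over seeds", {
  p <- sim_params()
  n_seeds <- 20
  est <- sapply(seq_len(n_seeds), function(s) {
    exc <- speed_tuning_from_series(
      simulate_speed_series(p, default_speed_grid(), "exc_current", seed = 100 + s))
    inh <- speed_tuning_from_series(
      simulate_speed_series(p, default_speed_grid(), "inh_current", seed = 300 + s))
    c(tuning_peak_fit(exc)$peak_x, tuning_peak_fit(inh)$peak_x)
  })
  expect_lt(abs(mean(est[1, ]) / p$exc_peak_speed - 1), 0.05)
  expect_lt(abs(mean(est[2, ]) / p$inh_peak_speed - 1), 0.05)
})
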