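# shared fixtures, built in code

# a current sweep with a flat baseline then a constant response plateau
flat_step_trace <- function(baseline_pA = 0, step_pA = 10, fs = 1000,
                            pre_s = 0.5, stim_s = 5, post_s = 0.5,
                            holding_mV = 20) {
  n <- round((pre_s + stim_s + post_s) * fs) + 1
  t <- (seq_len(n) - 1) / fs
  v <- rep(baseline_pA, n)
  v[t >= pre_s & t <= pre_s + stim_s] <- baseline_pA + step_pA
  sweep_trace(v, fs, pre_s, pre_s + stim_s, holding_mV = holding_mV)
}

# a tuning curve straight from mean values (single pseudo-trial)
curve_from_means <- function(x, means, units = "pC") {
  build_tuning_curve(stats::setNames(lapply(seq_along(x), function(i)
    c(means[i], means[i])), x), units = units)
}

noiseless_params <- function(...) {
  sim_params(current_noise_pA = 0, trial_gain_cv = 0, opto_noise_pA = 0,
             fluo_noise = 0, roi_pref_jitter_deg = 0,
             roi_selectivity_sdlog = 0, ...)
}

eight_dirs <- seq(0, 315, by = 45)

grating_stims <- function(speed = 1520, dirs = eight_dirs) {
  lapply(dirs, function(d)
    stimulus_spec("grating", speed_um_s = speed, direction_deg = d))
}
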