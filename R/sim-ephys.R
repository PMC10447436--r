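#' Simulate a speed series of current sweeps or spike trains
#'
#' Generates, for each grating speed, `n_trials` voltage-clamp sweeps or
#' cell-attached spike trains whose underlying mean follows the generator's
#' log-Gaussian speed tuning (see [ephys_mean_response()]). Inhibitory
#' sweeps combine a stimulus-locked modulated component (one minor peak per
#' grating cycle, anti-phase to excitation) with a sustained plateau whose
#' weight grows with speed; excitation is purely modulated. Spike trains are
#' inhomogeneous Poisson with total rate set by the rectified E-I drive and
#' time course locked to the excitatory modulation.
#'
#' Sign convention: excitatory currents are inward (negative pA) at -65 mV,
#' inhibitory currents outward (positive) at +20 mV, so charge transfer
#' preserves sign; tuning analyses use magnitudes.
#'
#' @param params A [sim_params()].
#' @param speeds Positive grating speeds (um/s).
#' @param modality `"spikes"`, `"exc_current"` or `"inh_current"`.
#' @param condition Pharmacological/chemogenetic condition; one of
#'   `"control"`, `"strychnine"`, `"gabazine"`, `"both"`, `"cno"`.
#' @param n_trials Trials per speed (default 3).
#' @param seed Seed for this call; defaults to `params$seed`. Identical
#'   parameters and seed give identical output.
#' @return A list with one element per speed, each a list with `stimulus`
#'   (a [stimulus_spec()]) and `trials` (list of [sweep_trace()] or
#'   [spike_train()]).
#' @export
simulate_speed_series <- function(params, speeds,
                                  modality = c("spikes", "exc_current", "inh_current"),
                                  condition = "control",
                                  n_trials = 3, seed = params$seed) {
  modality <- match.arg(modality)
  if (!length(speeds) || any(speeds <= 0)) stop("speeds must be nonempty and positive")
  condition <- match.arg(condition, c("control", "strychnine", "gabazine", "both", "cno"))
  mean_resp <- ephys_mean_response(params, speeds, modality, condition)
  withr::with_seed(seed, {
    lapply(seq_along(speeds), function(i) {
      stim <- stimulus_spec("grating", speed_um_s = speeds[i], n_trials = n_trials)
      trials <- lapply(seq_len(n_trials), function(k) {
        if (modality == "spikes") {
          .sim_spike_trial(params, stim, mean_resp[i])
        } else {
          .sim_current_trial(params, stim, mean_resp[i], modality)
        }
      })
      list(stimulus = stim, trials = trials)
    })
  })
}

# one voltage-clamp sweep: pre-stim baseline, stimulus-locked response, tail
.sim_current_trial <- function(params, stim, charge_pC, modality) {
  fs <- params$ephys_rate_hz
  t_on <- params$pre_stim_s
  t_off <- t_on + stim$duration_s
  n <- round((t_off + params$post_stim_s) * fs) + 1
  t <- (seq_len(n) - 1) / fs
  shape <- numeric(n)
  in_stim <- t >= t_on & t <= t_off
  ts <- t[in_stim] - t_on
  f <- temporal_frequency(stim)
  if (modality == "exc_current") {
    mod <- 0.5 * (1 - cos(2 * pi * f * ts))   # one peak per grating cycle
    base <- mod
    holding <- -65
    sign_fac <- -1                            # inward
  } else {
    mod <- 0.5 * (1 + cos(2 * pi * f * ts))   # anti-phase minor peaks
    p <- plateau_weight(params, stim$speed_um_s)
    base <- (1 - p) * mod + p                 # modulated + sustained plateau
    holding <- 20
    sign_fac <- 1                             # outward
  }
  area <- pracma::trapz(ts, base)
  if (area > 0) shape[in_stim] <- base / area
  gain <- max(0, 1 + stats::rnorm(1, 0, params$trial_gain_cv))
  values <- sign_fac * gain * charge_pC * shape +
    stats::rnorm(n, 0, params$current_noise_pA)
  sweep_trace(values, fs, t_on, t_off, holding_mV = holding,
              channel_kind = "current")
}

# one cell-attached trial: inhomogeneous Poisson locked to the excitatory
# modulation, expected total count = rectified E-I drive
.sim_spike_trial <- function(params, stim, expected_count) {
  t_on <- params$pre_stim_s
  t_off <- t_on + stim$duration_s
  len <- t_off + params$post_stim_s
  n_sp <- stats::rpois(1, expected_count)
  if (n_sp == 0) return(spike_train(numeric(0), len, t_on, t_off))
  f <- temporal_frequency(stim)
  # inverse-CDF sampling of the within-stimulus density prop. to 1-cos(2pi f t)
  grid <- seq(0, stim$duration_s, length.out = 4096)
  dens <- 0.5 * (1 - cos(2 * pi * f * grid))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  u <- sort(stats::runif(n_sp))
  times <- t_on + stats::approx(cdf, grid, xout = u, ties = "ordered", rule = 2)$y
  times <- sort(unique(times))
  spike_train(times, len, t_on, t_off)
}

#' Simulate one optogenetic pulse trial
#'
#' One 20 kHz voltage-clamp sweep with a 2 s pre-stimulus baseline, a
#' saturating-rise evoked current during the light pulse and exponential
#' decay after it. At +20 mV the evoked current is the outward glycinergic
#' IPSC; at -65 mV the inward glutamatergic EPSC. Pharmacological conditions
#' scale the evoked amplitude: `pr_block` (photoreceptor block) is the
#' reference; `glut_block` additionally removes the disynaptic fraction of
#' the IPSC (and abolishes the EPSC); `gly_block` leaves only a small
#' residue of the IPSC; `all_block` abolishes everything.
#'
#' @param params A [sim_params()].
#' @param pulse_duration_s Light pulse duration (s), > 0; 0.1 or 1 by default
#'   in the study conditions.
#' @param holding_mV Holding potential; `+20` (IPSC) or `-65` (EPSC).
#' @param condition `"pr_block"`, `"glut_block"`, `"gly_block"`, `"all_block"`.
#' @param seed Seed; defaults to `params$seed`.
#' @return A [sweep_trace()].
#' @export
simulate_opto_trial <- function(params, pulse_duration_s = 1, holding_mV = 20,
                                condition = c("pr_block", "glut_block",
                                              "gly_block", "all_block"),
                                seed = params$seed) {
  condition <- match.arg(condition)
  if (pulse_duration_s <= 0) stop("pulse_duration_s must be > 0")
  fs <- params$opto_rate_hz
  t_on <- params$opto_pre_s
  t_off <- t_on + pulse_duration_s
  n <- round((t_off + params$opto_post_s) * fs) + 1
  t <- (seq_len(n) - 1) / fs
  if (holding_mV > 0) {
    amp <- params$opto_ipsc_pA
    scale <- switch(condition,
                    pr_block = 1,
                    glut_block = 1 - params$opto_disyn_frac,
                    gly_block = params$opto_strych_resid,
                    all_block = 0)
    sign_fac <- 1
  } else {
    amp <- params$opto_epsc_pA
    scale <- switch(condition,
                    pr_block = 1,
                    glut_block = 0,     # EPSC is glutamatergic
                    gly_block = 1,      # unaffected by strychnine
                    all_block = 0)
    sign_fac <- -1
  }
  evoked <- numeric(n)
  rise <- t >= t_on & t <= t_off
  evoked[rise] <- 1 - exp(-(t[rise] - t_on) / params$opto_rise_tau_s)
  after <- t > t_off
  peak_at_off <- 1 - exp(-pulse_duration_s / params$opto_rise_tau_s)
  evoked[after] <- peak_at_off * exp(-(t[after] - t_off) / params$opto_decay_tau_s)
  withr::with_seed(seed, {
    values <- sign_fac * amp * scale * evoked +
      stats::rnorm(n, 0, params$opto_noise_pA)
    sweep_trace(values, fs, t_on, t_off, holding_mV = holding_mV,
                channel_kind = "current")
  })
}
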