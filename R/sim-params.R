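#' Synthetic-recording generator parameters
#'
#' Complete parameterization of the synthetic data generator. Defaults are
#' calibrated to the population summary values of the study conditions:
#' spiking optimum near 150 um/s (absolute maximum ~96 spikes per 5 s
#' stimulus), excitatory charge peaking at 710 um/s (490 pC), inhibitory
#' charge peaking at 1220 um/s (2200 pC), optogenetic IPSC peaks of 43/26 pA
#' for 1/0.1 s pulses and EPSC peaks of 9 pA, population calcium selectivity
#' DSI = 0.28 and OSI = 0.38, and center-surround area-response profiles with
#' surround suppression to 8% (spots) and 20% (grating patches) of maximum.
#'
#' Speed-tuning curves use a log-Gaussian generator convention
#' `G(v) = exp(-(ln v - ln v0)^2 / (2 sigma^2))`; the excitatory width is set
#' by the printed descending half-maximum (2290 um/s) and the inhibitory
#' width so that its half-maximum falls beyond 2900 um/s. Spiking is a
#' rectified linear excitation-minus-inhibition drive fed through an
#' inhomogeneous Poisson process: inhibition, not intrinsic spiking
#' machinery, sets the fast-speed cutoff.
#'
#' @param ... Named overrides of any default listed below.
#' @param seed Integer seed; every `simulate_*` draw derives from it.
#' @return An object of class `sim_params` (a validated list).
#' @details Key fields:
#' \describe{
#'   \item{exc_peak_speed, exc_log_width, exc_amp_pC}{log-Gaussian excitatory
#'     charge tuning (710 um/s, 0.995, 490 pC).}
#'   \item{inh_peak_speed, inh_log_width, inh_amp_pC}{inhibitory charge
#'     tuning (1220 um/s, 0.85, 2200 pC).}
#'   \item{inh_plateau_frac, plateau_mid_speed, plateau_log_slope}{weight of
#'     the sustained (non-modulated) inhibitory component; a logistic in
#'     ln(v) with midpoint at the E/I crossover speed (700 um/s).}
#'   \item{glycine_frac, gaba_frac}{additive partition of inhibition
#'     (0.57/0.43, sums to 1); strychnine removes the glycinergic part,
#'     SR95531 (gabazine) the GABAergic part, so the simulated strychnine
#'     decrease in inhibitory charge equals `glycine_frac`.}
#'   \item{vglut3_frac_of_glycine}{fraction of the glycinergic component
#'     silenced by chemogenetic (CNO/DREADD) suppression (0.75, so the CNO
#'     decrease is 0.75 * 0.57 = 43 percent of total inhibition).}
#'   \item{ei_weight, spike_gain, spike_threshold}{rectified drive
#'     `gain * max(0, E(v) - w * I(v) - threshold)` giving the expected
#'     spike count per stimulus.}
#'   \item{noise ...}{`current_noise_pA`, `opto_noise_pA`, `fluo_noise`
#'     per-sample Gaussian noise; `trial_gain_cv` multiplicative
#'     trial-to-trial gain variability of current responses.}
#'   \item{opto ...}{IPSC/EPSC amplitudes and saturating-rise/decay time
#'     constants; `opto_disyn_frac` is the disynaptic (glutamate-relayed)
#'     fraction of the evoked IPSC, `opto_strych_resid` the residue after
#'     glycinergic blockade.}
#'   \item{ca ...}{calcium speed tuning (monotone-rising log-Gaussian peaked
#'     at 1520 um/s), direction/orientation tuning targets `ca_dsi`/`ca_osi`
#'     with preferred angles, onset/decay kinetics, per-ROI preferred-angle
#'     jitter, and center-surround area-response parameters per stimulus
#'     kind.}
#' }
#' @export
sim_params <- function(..., seed = 1L) {
  p <- list(
    # speed tuning of synaptic charge (pC) and spiking
    exc_peak_speed = 710, exc_log_width = 0.995, exc_amp_pC = 490,
    inh_peak_speed = 1220, inh_log_width = 0.85, inh_amp_pC = 2200,
    inh_plateau_frac = 0.8, plateau_mid_speed = 700, plateau_log_slope = 0.5,
    glycine_frac = 0.57, gaba_frac = 0.43, vglut3_frac_of_glycine = 0.75,
    ei_weight = 0.745, spike_gain = 1.41, spike_threshold = 0,
    # recording parameters and noise
    ephys_rate_hz = 10000, pre_stim_s = 0.5, post_stim_s = 0.5,
    current_noise_pA = 5, trial_gain_cv = 0.1,
    # optogenetics (20 kHz, 2 s pre-stimulus baseline)
    opto_rate_hz = 20000, opto_pre_s = 2, opto_post_s = 1,
    opto_ipsc_pA = 43, opto_epsc_pA = 9,
    opto_rise_tau_s = 0.1078, opto_decay_tau_s = 0.15,
    opto_disyn_frac = 0.21, opto_strych_resid = 0.01,
    opto_noise_pA = 8,
    # calcium imaging (15 Hz)
    frame_rate_hz = 15,
    ca_peak_speed = 1520, ca_log_width = 1.0, ca_amp = 1.2,
    ca_dsi = 0.28, ca_osi = 0.38,
    pref_direction_deg = 198, pref_orientation_deg = 56,
    roi_pref_jitter_deg = 10, roi_selectivity_sdlog = 0.5,
    ca_onset_tau_s = 1.0, ca_decay_tau_s = 0.5,
    ca_f0 = 100, fluo_noise = 2,
    area_center_sigma_um = c(spot = 149, grating = 234),
    area_surround_sigma_um = c(spot = 356, grating = 476),
    surround_weight = c(spot = 0.954, grating = 0.916),
    um_per_deg = 30,
    seed = as.integer(seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown sim_params field(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  amps <- c(p$exc_amp_pC, p$inh_amp_pC, p$opto_ipsc_pA, p$opto_epsc_pA, p$ca_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (abs(p$glycine_frac + p$gaba_frac - 1) > 1e-8)
    stop("glycine_frac + gaba_frac must equal 1")
  if (p$inh_plateau_frac < 0 || p$inh_plateau_frac > 1)
    stop("inh_plateau_frac must be in [0, 1]")
  if (p$vglut3_frac_of_glycine < 0 || p$vglut3_frac_of_glycine > 1)
    stop("vglut3_frac_of_glycine must be in [0, 1]")
  if (p$exc_log_width <= 0 || p$inh_log_width <= 0 || p$ca_log_width <= 0)
    stop("tuning widths must be > 0")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> seed", x$seed, "\n")
  cat(sprintf("  exc: peak %g um/s, width %g, amp %g pC\n",
              x$exc_peak_speed, x$exc_log_width, x$exc_amp_pC))
  cat(sprintf("  inh: peak %g um/s, width %g, amp %g pC, plateau %g\n",
              x$inh_peak_speed, x$inh_log_width, x$inh_amp_pC, x$inh_plateau_frac))
  cat(sprintf("  partition: glycine %g / GABA %g; VGluT3-of-glycine %g\n",
              x$glycine_frac, x$gaba_frac, x$vglut3_frac_of_glycine))
  cat(sprintf("  spikes: gain %g, E-I weight %g\n", x$spike_gain, x$ei_weight))
  cat(sprintf("  calcium: peak %g um/s, DSI %g / OSI %g\n",
              x$ca_peak_speed, x$ca_dsi, x$ca_osi))
  invisible(x)
}

# unnormalized log-Gaussian tuning over speed
.log_gauss <- function(v, peak, width) exp(-(log(v) - log(peak))^2 / (2 * width^2))

# multiplicative scaling of total inhibition under a pharmacological or
# chemogenetic condition (additive component partition)
condition_inh_scale <- function(params, condition) {
  switch(condition,
         control    = 1,
         strychnine = 1 - params$glycine_frac,
         gabazine   = 1 - params$gaba_frac,
         both       = 0,
         cno        = 1 - params$vglut3_frac_of_glycine * params$glycine_frac,
         stop("unknown condition: ", condition))
}

#' Noiseless mean ephys response of the generator
#'
#' Closed-form expected response at each speed: excitatory/inhibitory charge
#' magnitude (pC) or expected spike count, under a pharmacological condition.
#' This is the analytic tuning the simulator draws around, exposed so
#' pipeline output can be checked against it.
#'
#' @param params A [sim_params()].
#' @param speeds Positive speeds (um/s).
#' @param modality `"spikes"`, `"exc_current"` or `"inh_current"`.
#' @param condition One of `"control"`, `"strychnine"`, `"gabazine"`,
#'   `"both"`, `"cno"`.
#' @return Numeric vector, same length as `speeds`.
#' @export
ephys_mean_response <- function(params, speeds,
                                modality = c("spikes", "exc_current", "inh_current"),
                                condition = "control") {
  modality <- match.arg(modality)
  if (any(speeds <= 0)) stop("speeds must be positive")
  scale_i <- condition_inh_scale(params, condition)
  E <- params$exc_amp_pC * .log_gauss(speeds, params$exc_peak_speed, params$exc_log_width)
  I <- scale_i * params$inh_amp_pC *
    .log_gauss(speeds, params$inh_peak_speed, params$inh_log_width)
  switch(modality,
         exc_current = E,
         inh_current = I,
         spikes = params$spike_gain *
           pmax(0, E - params$ei_weight * I - params$spike_threshold))
}

# plateau (sustained inhibition) weight: logistic in ln(v)
plateau_weight <- function(params, v) {
  params$inh_plateau_frac *
    stats::plogis((log(v) - log(params$plateau_mid_speed)) / params$plateau_log_slope)
}
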