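#' Simulate a set of dendritic ROI fluorescence traces
#'
#' Generates one continuous 15 Hz fluorescence trace per ROI for a session
#' in which the given stimuli are each presented for `n_trials` trials
#' (trials interleaved, gray inter-stimulus intervals between
#' presentations). Each ROI's noiseless response amplitude factorizes as
#' `S(speed) * D(direction) * A(diameter)`:
#' * `S` is a monotone-rising log-Gaussian over the tested range, peaked
#'   near 1520 um/s (gratings only; spots use `S = 1`);
#' * `D(theta) = 1 + k_DS cos(theta - theta_pref) + k_OS cos(2 (theta -
#'   theta_ori))` with `k_DS = 2 * ca_dsi`, `k_OS = 2 * ca_osi`, so the
#'   vector-sum indices of the noiseless tuning equal `ca_dsi`/`ca_osi`
#'   exactly; per-ROI preferred angles are jittered around the population
#'   means and per-ROI harmonic strengths scatter (mean-1 lognormal,
#'   `roi_selectivity_sdlog`) so classification fractions at the 0.2
#'   criterion are realistic;
#' * `A` is a center-surround difference of two saturating area integrals
#'   with stimulus-kind-specific surround weight (full field = `Inf`
#'   diameter).
#'
#' Fluorescence follows a saturating onset ramp (barely detectable in the
#' first second, ~2 s to approach asymptote) and exponential decay after
#' stimulus offset, riding on baseline `ca_f0` with Gaussian frame noise.
#'
#' @param params A [sim_params()].
#' @param stimuli List of [stimulus_spec()] (gratings, masked gratings or
#'   spots). All must share the acquisition frame rate: a stimulus carrying
#'   a `frame_rate_hz` attribute different from `params$frame_rate_hz`
#'   raises an inconsistent-acquisition error.
#' @param n_rois Number of ROIs (>= 1).
#' @param n_trials Trials per stimulus (default 3).
#' @param fov_id Field-of-view label.
#' @param seed Seed; defaults to `params$seed`.
#' @return An object of class `roi_trace_set`: list with `roi_ids`, `traces`
#'   (one fluorescence [sweep_trace()] per ROI), `stimulus_table` (one row
#'   per presentation with timing), `frame_rate_hz` and `fov_id`.
#' @export
simulate_roi_traces <- function(params, stimuli, n_rois, n_trials = 3,
                                fov_id = "fov1", seed = params$seed) {
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (!length(stimuli)) stop("stimuli must be nonempty")
  for (s in stimuli) {
    fr <- attr(s, "frame_rate_hz")
    if (!is.null(fr) && fr != params$frame_rate_hz)
      stop("inconsistent acquisition: stimuli recorded at mixed frame rates")
  }
  fs <- params$frame_rate_hz
  # presentation table: trials interleaved across stimuli
  rows <- list()
  t_cursor <- 0
  idx <- 0
  for (trial in seq_len(n_trials)) {
    for (k in seq_along(stimuli)) {
      s <- stimuli[[k]]
      idx <- idx + 1
      t_on <- t_cursor + s$interstim_s
      rows[[idx]] <- data.frame(
        stim_index = k, kind = s$kind, cycle_um = s$cycle_um,
        speed_um_s = s$speed_um_s, direction_deg = s$direction_deg,
        diameter_um = s$diameter_um, duration_s = s$duration_s,
        t_on_s = t_on, t_off_s = t_on + s$duration_s, trial = trial)
      t_cursor <- t_on + s$duration_s
    }
  }
  stim_table <- do.call(rbind, rows)
  total_s <- t_cursor + 2   # short tail
  n_frames <- ceiling(total_s * fs)
  t <- (seq_len(n_frames) - 1) / fs

  withr::with_seed(seed, {
    # per-ROI selectivity strength: independent mean-1 lognormal factors for
    # the direction and orientation harmonics, so individual ROIs scatter
    # around the population-mean DSI/OSI and a realistic minority falls
    # below the 0.2 classification criterion
    s <- params$roi_selectivity_sdlog
    k_ds <- 2 * params$ca_dsi * exp(stats::rnorm(n_rois, -s^2 / 2, s))
    k_os <- 2 * params$ca_osi * exp(stats::rnorm(n_rois, -s^2 / 2, s))
    pref_dir <- params$pref_direction_deg +
      stats::rnorm(n_rois, 0, params$roi_pref_jitter_deg)
    pref_ori <- params$pref_orientation_deg +
      stats::rnorm(n_rois, 0, params$roi_pref_jitter_deg)
    roi_gain <- exp(stats::rnorm(n_rois, 0, 0.2))

    traces <- lapply(seq_len(n_rois), function(j) {
      dff <- numeric(n_frames)
      for (r in seq_len(nrow(stim_table))) {
        row <- stim_table[r, ]
        amp <- roi_gain[j] * .ca_amplitude(params, row, pref_dir[j], pref_ori[j],
                                           k_ds[j], k_os[j])
        if (amp == 0) next
        resp <- t >= row$t_on_s
        tr <- t[resp] - row$t_on_s
        kern <- ifelse(tr <= row$duration_s,
                       1 - exp(-tr / params$ca_onset_tau_s),
                       (1 - exp(-row$duration_s / params$ca_onset_tau_s)) *
                         exp(-(tr - row$duration_s) / params$ca_decay_tau_s))
        dff[resp] <- dff[resp] + amp * kern
      }
      f <- params$ca_f0 * (1 + dff) + stats::rnorm(n_frames, 0, params$fluo_noise)
      sweep_trace(f, fs, stim_table$t_on_s[1], stim_table$t_off_s[nrow(stim_table)],
                  channel_kind = "fluorescence")
    })
    structure(
      list(roi_ids = sprintf("roi%03d", seq_len(n_rois)), traces = traces,
           stimulus_table = stim_table, frame_rate_hz = fs, fov_id = fov_id),
      class = "roi_trace_set")
  })
}

# asymptotic dF/F amplitude for one presentation of one ROI
.ca_amplitude <- function(params, row, pref_dir, pref_ori, k_ds, k_os) {
  kind_key <- if (row$kind == "spot") "spot" else "grating"
  a <- .area_integral(row$diameter_um,
                      params$area_center_sigma_um[[kind_key]],
                      params$area_surround_sigma_um[[kind_key]],
                      params$surround_weight[[kind_key]])
  if (row$kind == "spot") {
    # spots: no motion; amplitude set by the area profile alone
    amax <- .area_profile_max(params, "spot")
    return(2.3 / amax * max(0, a))
  }
  S <- .log_gauss(max(row$speed_um_s, 1e-6), params$ca_peak_speed, params$ca_log_width)
  D <- 1 + k_ds * cos((row$direction_deg - pref_dir) * pi / 180) +
    k_os * cos(2 * (row$direction_deg - pref_ori) * pi / 180)
  a_ff <- .area_integral(Inf, params$area_center_sigma_um[["grating"]],
                         params$area_surround_sigma_um[["grating"]],
                         params$surround_weight[["grating"]])
  gain <- params$ca_amp / a_ff   # full-field optimum-speed response = ca_amp
  gain * S * max(0, D) * max(0, a)
}

# difference of two saturating Gaussian area integrals
.area_integral <- function(d, sc, ss, w) {
  cen <- 1 - exp(-(d / sc)^2)
  sur <- 1 - exp(-(d / ss)^2)
  cen[!is.finite(d)] <- 1; sur[!is.finite(d)] <- 1
  cen - w * sur
}

.area_profile_max <- function(params, kind) {
  d <- seq(10, 3000, by = 2)
  max(.area_integral(d, params$area_center_sigma_um[[kind]],
                     params$area_surround_sigma_um[[kind]],
                     params$surround_weight[[kind]]))
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %s: %d ROIs, %d presentations @ %g Hz\n",
              x$fov_id, length(x$roi_ids), nrow(x$stimulus_table),
              x$frame_rate_hz))
  invisible(x)
}
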