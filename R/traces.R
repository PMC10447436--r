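#' Uniformly sampled recording sweep
#'
#' Container for one current (voltage clamp) or fluorescence (two-photon)
#' sweep, with stimulus timing carried alongside the samples. Times are in
#' seconds from sweep start; sample 1 sits at t = 0.
#'
#' @param values Numeric vector of samples (pA for currents, arbitrary
#'   fluorescence units for imaging). Must be finite.
#' @param sample_rate_hz Sampling rate (Hz), > 0.
#' @param t_stim_on_s,t_stim_off_s Stimulus onset/offset relative to sweep
#'   start; `0 <= on < off <= sweep length`.
#' @param holding_mV Holding potential (mV) for voltage-clamp sweeps, or
#'   `NULL` for traces without one (e.g. fluorescence).
#' @param channel_kind `"current"` or `"fluorescence"`.
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(values, sample_rate_hz, t_stim_on_s, t_stim_off_s,
                        holding_mV = NULL,
                        channel_kind = c("current", "fluorescence")) {
  channel_kind <- match.arg(channel_kind)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("sweep values must be finite")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be > 0")
  len_s <- length(values) / sample_rate_hz
  if (t_stim_on_s < 0 || t_stim_on_s >= t_stim_off_s || t_stim_off_s > len_s + 1e-9)
    stop("stimulus window must satisfy 0 <= on < off <= sweep length")
  structure(
    list(values = values, sample_rate_hz = sample_rate_hz,
         t_stim_on_s = t_stim_on_s, t_stim_off_s = t_stim_off_s,
         holding_mV = holding_mV, channel_kind = channel_kind),
    class = "sweep_trace")
}

#' Sample times of a sweep
#' @param trace A [sweep_trace()].
#' @return Numeric vector of times (s), starting at 0.
#' @export
sweep_times <- function(trace) {
  stopifnot(inherits(trace, "sweep_trace"))
  (seq_along(trace$values) - 1) / trace$sample_rate_hz
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("<sweep_trace> %s, %d samples @ %g Hz (%.3g s), stim [%g, %g] s%s\n",
              x$channel_kind, length(x$values), x$sample_rate_hz,
              length(x$values) / x$sample_rate_hz,
              x$t_stim_on_s, x$t_stim_off_s,
              if (is.null(x$holding_mV)) "" else sprintf(", Vhold %g mV", x$holding_mV)))
  invisible(x)
}

#' Spike train from a cell-attached recording
#'
#' @param spike_times_s Strictly increasing spike times (s) within
#'   `[0, sweep_length_s]`.
#' @param sweep_length_s Sweep duration (s).
#' @param t_stim_on_s,t_stim_off_s Optional stimulus timing metadata.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times_s, sweep_length_s,
                        t_stim_on_s = NULL, t_stim_off_s = NULL) {
  spike_times_s <- as.numeric(spike_times_s)
  if (length(spike_times_s) > 1 && any(diff(spike_times_s) <= 0))
    stop("spike times must be strictly increasing")
  if (length(spike_times_s) &&
      (min(spike_times_s) < 0 || max(spike_times_s) > sweep_length_s))
    stop("spike times must lie within [0, sweep_length_s]")
  structure(
    list(spike_times_s = spike_times_s, sweep_length_s = sweep_length_s,
         t_stim_on_s = t_stim_on_s, t_stim_off_s = t_stim_off_s),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in %g s\n",
              length(x$spike_times_s), x$sweep_length_s))
  invisible(x)
}

#' Average repeated sweeps sample-by-sample
#'
#' Trial averaging before smoothing and peak extraction, the order used for
#' evoked-current quantification.
#'
#' @param sweeps List of [sweep_trace()]s with identical sampling and
#'   stimulus timing.
#' @return A [sweep_trace()] holding the pointwise mean.
#' @export
average_sweeps <- function(sweeps) {
  stopifnot(length(sweeps) >= 1)
  ref <- sweeps[[1]]
  for (s in sweeps[-1]) {
    if (length(s$values) != length(ref$values) ||
        s$sample_rate_hz != ref$sample_rate_hz)
      stop("sweeps must share length and sampling rate")
  }
  ref$values <- rowMeans(vapply(sweeps, function(s) s$values,
                                numeric(length(ref$values))))
  ref
}

# indices of samples with t in [from, to) -- half-open window convention
.window_idx <- function(trace, from, to, closed_right = FALSE) {
  t <- sweep_times(trace)
  len <- length(trace$values) / trace$sample_rate_hz
  if (from < 0 || to > len + 1e-9 || from >= to)
    stop("window [", from, ", ", to, ") outside sweep or inverted")
  if (closed_right) which(t >= from - 1e-12 & t <= to + 1e-12)
  else which(t >= from - 1e-12 & t < to - 1e-12)
}
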