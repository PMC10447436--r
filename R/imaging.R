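#' Delta-F/F of one stimulus presentation
#'
#' The baseline fluorescence F0 is the mean brightness over the 0.5 s
#' (exactly `floor(0.5 * frame_rate)` frames, 7 at 15 Hz) immediately before
#' the presentation; F0 is computed per presentation, never globally. The
#' returned sweep covers the presentation frames (`[t_on, t_off)`).
#'
#' @param trace A fluorescence [sweep_trace()] (one ROI's full-session
#'   trace).
#' @param stim_row One row of a `roi_trace_set` stimulus table (needs
#'   `t_on_s` and `t_off_s`).
#' @return Numeric vector of per-frame `(F - F0)/F0` with attributes
#'   `frame_rate_hz` and `f0`.
#' @export
dff <- function(trace, stim_row) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (trace$channel_kind != "fluorescence")
    stop("dff requires a fluorescence trace")
  fs <- trace$sample_rate_hz
  n_base <- floor(0.5 * fs)
  t <- sweep_times(trace)
  i_on <- which(t >= stim_row$t_on_s - 1e-9)[1]
  if (is.na(i_on) || i_on - n_base < 1)
    stop("need 0.5 s of pre-stimulus baseline")
  f0 <- mean(trace$values[(i_on - n_base):(i_on - 1)])
  if (!is.finite(f0) || f0 <= 0) stop("invalid baseline: F0 <= 0")
  resp <- which(t >= stim_row$t_on_s - 1e-9 & t < stim_row$t_off_s - 1e-9)
  out <- (trace$values[resp] - f0) / f0
  attr(out, "frame_rate_hz") <- fs
  attr(out, "f0") <- f0
  out
}

#' Time-averaged response of a delta-F/F sweep
#'
#' @param dff_sweep Output of [dff()].
#' @param window `"full"` (whole presentation), `"first_2s"` (spots) or
#'   `"avg_5s"` (gratings).
#' @return Scalar mean delta-F/F.
#' @export
time_avg_response <- function(dff_sweep, window = c("full", "first_2s", "avg_5s")) {
  window <- match.arg(window)
  fs <- attr(dff_sweep, "frame_rate_hz")
  if (is.null(fs)) stop("dff_sweep must carry a frame_rate_hz attribute")
  n <- switch(window,
              full = length(dff_sweep),
              first_2s = round(2 * fs),
              avg_5s = round(5 * fs))
  if (n > length(dff_sweep))
    stop("averaging window exceeds the presentation")
  mean(dff_sweep[seq_len(n)])
}

#' ROI responsiveness filter
#'
#' A ROI is kept when its time-averaged response strictly surpasses
#' `threshold` in at least `min_count` of the presentations. The study
#' conditions use thresholds of 0.3-0.6 delta-F/F and counts of 3 or 6 out
#' of 24 presentations; values outside that band are allowed but flagged
#' with a warning.
#'
#' @param responses Numeric vector of time-averaged responses, one per
#'   presentation.
#' @param threshold Delta-F/F threshold (strict `>`).
#' @param min_count Minimum number of supra-threshold presentations.
#' @param n_presentations Expected presentation count (default 24); a
#'   mismatch is an error.
#' @return Logical flag.
#' @export
roi_responsive <- function(responses, threshold = 0.4, min_count = 3,
                           n_presentations = length(responses)) {
  if (length(responses) != n_presentations)
    stop("expected ", n_presentations, " responses, got ", length(responses))
  if (threshold < 0.3 || threshold > 0.6)
    warning("threshold ", threshold, " outside the usual 0.3-0.6 band")
  sum(responses > threshold) >= min_count
}

#' Direction and orientation selectivity from 8-direction responses
#'
#' Normalized circular-harmonic vector sums:
#' `DSI = |sum R_k exp(i theta_k)| / sum R_k` (first harmonic) and
#' `OSI = |sum R_k exp(2 i theta_k)| / sum R_k` (second harmonic), with the
#' preferred direction the argument of the first-harmonic sum and the
#' preferred orientation half the argument of the second-harmonic sum,
#' reduced mod 180. Negative mean responses are clipped to 0 before the
#' sums so both indices land in `[0, 1]`; clipping is reported via the
#' `clipped` field. A ROI is classified DS/OS when the corresponding index
#' is >= `criterion` (default 0.2; strictness is configurable).
#'
#' @param responses Mean responses in each of 8 equally spaced directions.
#' @param directions_deg The 8 directions (deg); default 0, 45, ..., 315.
#' @param criterion Classification threshold (default 0.2).
#' @param strict If `TRUE` classify on `> criterion` instead of `>=`.
#' @return An object of class `direction_tuning` with fields
#'   `directions_deg`, `responses`, `dsi`, `osi`, `pref_direction_deg`
#'   (in `[0, 360)`), `pref_orientation_deg` (in `[0, 180)`), `is_ds`,
#'   `is_os`, `clipped`. If all responses are 0 the indices are `NA` and
#'   both flags `FALSE`.
#' @export
dsi_osi <- function(responses, directions_deg = seq(0, 315, by = 45),
                    criterion = 0.2, strict = FALSE) {
  if (length(responses) != 8 || length(directions_deg) != 8)
    stop("need responses in 8 directions")
  gaps <- sort(diff(sort(directions_deg %% 360)))
  if (any(abs(gaps - 45) > 1e-6))
    stop("directions must be 8 equally spaced angles")
  clipped <- any(responses < 0)
  r <- pmax(responses, 0)
  total <- sum(r)
  th <- directions_deg * pi / 180
  if (total == 0) {
    return(structure(list(directions_deg = directions_deg, responses = r,
                          dsi = NA_real_, osi = NA_real_,
                          pref_direction_deg = NA_real_,
                          pref_orientation_deg = NA_real_,
                          is_ds = FALSE, is_os = FALSE, clipped = clipped),
                     class = "direction_tuning"))
  }
  v1 <- sum(r * exp(1i * th))
  v2 <- sum(r * exp(2i * th))
  dsi <- Mod(v1) / total
  osi <- Mod(v2) / total
  meets <- function(ix) if (strict) ix > criterion else ix >= criterion
  structure(list(
    directions_deg = directions_deg, responses = r,
    dsi = dsi, osi = osi,
    pref_direction_deg = (Arg(v1) * 180 / pi) %% 360,
    pref_orientation_deg = (Arg(v2) * 90 / pi) %% 180,
    is_ds = meets(dsi), is_os = meets(osi), clipped = clipped),
    class = "direction_tuning")
}

#' @export
print.direction_tuning <- function(x, ...) {
  cat(sprintf("<direction_tuning> DSI %.3f (%s), OSI %.3f (%s), pref dir %.1f deg, pref ori %.1f deg\n",
              x$dsi, if (x$is_ds) "DS" else "-", x$osi,
              if (x$is_os) "OS" else "-",
              x$pref_direction_deg, x$pref_orientation_deg))
  invisible(x)
}

#' Area-response summary
#'
#' @param responses Named numeric vector: names are stimulus diameters (um),
#'   values time-averaged responses; >= 3 diameters.
#' @return List with `optimal_diameter_um` (argmax) and
#'   `suppression_index` = response at the largest diameter / maximum
#'   response (1 = no surround suppression).
#' @export
area_response <- function(responses) {
  d <- as.numeric(names(responses))
  if (length(d) < 3 || any(is.na(d))) stop("need responses at >= 3 named diameters")
  ord <- order(d)
  d <- d[ord]; r <- as.numeric(responses)[ord]
  if (max(r) <= 0) stop("degenerate area-response: maximum <= 0")
  list(optimal_diameter_um = d[which.max(r)],
       suppression_index = r[length(r)] / max(r))
}

#' Circular mean and SEM of angles
#'
#' Resultant-vector circular mean; dispersion is the circular standard
#' deviation `sqrt(-2 ln Rbar)` divided by `sqrt(n)`. For orientation data
#' (period 180 deg) angles are doubled before averaging and the mean halved
#' afterwards.
#'
#' @param angles_deg Angles (deg).
#' @param orientation If `TRUE`, treat as axial data with period 180 deg.
#' @return List with `mean_deg` (in `[0, 360)` or `[0, 180)`), `sem_deg`,
#'   `resultant` (mean vector length).
#' @export
circular_mean <- function(angles_deg, orientation = FALSE) {
  if (!length(angles_deg)) stop("no angles")
  mult <- if (orientation) 2 else 1
  z <- exp(1i * mult * angles_deg * pi / 180)
  zbar <- mean(z)
  rbar <- Mod(zbar)
  period <- 360 / mult
  mu <- (Arg(zbar) * 180 / pi / mult) %% period
  if (period - mu < 1e-9) mu <- 0   # guard against wrap to the period itself
  csd <- if (rbar > 0) sqrt(-2 * log(rbar)) * 180 / pi / mult else NA_real_
  list(mean_deg = mu, sem_deg = csd / sqrt(length(angles_deg)), resultant = rbar)
}

#' Classification fractions from OS/DS counts
#'
#' Given the number of orientation-selective, direction-selective and
#' unselective ROIs, computes the number meeting both criteria by
#' inclusion-exclusion (`os + ds - (total - neither)`) and the population
#' fractions. Percentages are reported at full precision with rounded
#' integer companions.
#'
#' @param n_os,n_ds,n_neither,n_total Counts.
#' @return data.frame with rows `os`, `ds`, `both`, `neither`: `count`,
#'   `pct` (exact), `pct_rounded`.
#' @export
classification_summary <- function(n_os, n_ds, n_neither, n_total) {
  n_any <- n_total - n_neither
  n_both <- n_os + n_ds - n_any
  if (n_both < 0 || n_both > min(n_os, n_ds))
    stop("inconsistent counts")
  counts <- c(os = n_os, ds = n_ds, both = n_both, neither = n_neither)
  data.frame(class = names(counts), count = as.integer(counts),
             pct = 100 * counts / n_total,
             pct_rounded = round(100 * counts / n_total),
             row.names = NULL)
}

#' Field-of-view population summary of direction tunings
#'
#' Tabulates OS/DS/both/neither fractions (both by direct intersection
#' count) and the circular mean +/- circular SEM of the preferred
#' orientations of OS ROIs and preferred directions of DS ROIs, plus polar
#' histogram counts with configurable bin width.
#'
#' @param tunings List of `direction_tuning` objects (>= 1 classified ROI).
#' @param bin_deg Polar histogram bin width (deg), default 15.
#' @return An object of class `fov_summary`: `classification` (see
#'   [classification_summary()]), `pref_orientation` / `pref_direction`
#'   (circular stats over the OS / DS subsets), `ori_hist` / `dir_hist`
#'   (bin counts), `n_rois`.
#' @export
fov_summary <- function(tunings, bin_deg = 15) {
  if (!length(tunings)) stop("no ROI tunings")
  is_os <- vapply(tunings, function(t) isTRUE(t$is_os), TRUE)
  is_ds <- vapply(tunings, function(t) isTRUE(t$is_ds), TRUE)
  n <- length(tunings)
  cls <- classification_summary(sum(is_os), sum(is_ds),
                                sum(!is_os & !is_ds), n)
  cls$count[cls$class == "both"] <- sum(is_os & is_ds)  # direct intersection
  oris <- vapply(tunings[is_os], function(t) t$pref_orientation_deg, 0)
  dirs <- vapply(tunings[is_ds], function(t) t$pref_direction_deg, 0)
  hist_counts <- function(a, period) {
    edges <- seq(0, period, by = bin_deg)
    if (!length(a)) return(stats::setNames(integer(length(edges) - 1),
                                           utils::head(edges, -1)))
    tabulate(findInterval(a %% period, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  }
  structure(list(
    n_rois = n,
    classification = cls,
    pref_orientation = if (length(oris)) circular_mean(oris, orientation = TRUE) else NULL,
    pref_direction = if (length(dirs)) circular_mean(dirs) else NULL,
    ori_hist = hist_counts(oris, 180),
    dir_hist = hist_counts(dirs, 360),
    bin_deg = bin_deg), class = "fov_summary")
}

#' @export
print.fov_summary <- function(x, ...) {
  cat(sprintf("<fov_summary> %d ROIs\n", x$n_rois))
  print(x$classification, row.names = FALSE)
  if (!is.null(x$pref_orientation))
    cat(sprintf("  preferred orientation %.1f +/- %.1f deg\n",
                x$pref_orientation$mean_deg, x$pref_orientation$sem_deg))
  if (!is.null(x$pref_direction))
    cat(sprintf("  preferred direction %.1f +/- %.1f deg\n",
                x$pref_direction$mean_deg, x$pref_direction$sem_deg))
  invisible(x)
}

#' Per-ROI time-averaged responses for every presentation
#'
#' Convenience extraction: applies [dff()] and [time_avg_response()] to
#' every (ROI, presentation) pair of a [simulate_roi_traces()] set.
#'
#' @param rts A `roi_trace_set`.
#' @param window Averaging window, see [time_avg_response()].
#' @return data.frame with `roi_id`, presentation metadata and `response`.
#' @export
roi_responses <- function(rts, window = "full") {
  stopifnot(inherits(rts, "roi_trace_set"))
  st <- rts$stimulus_table
  out <- do.call(rbind, lapply(seq_along(rts$roi_ids), function(j) {
    resp <- vapply(seq_len(nrow(st)), function(r)
      time_avg_response(dff(rts$traces[[j]], st[r, ]), window), 0)
    cbind(data.frame(roi_id = rts$roi_ids[j]), st, response = resp)
  }))
  rownames(out) <- NULL
  out
}

#' Direction tuning of every ROI in a field of view
#'
#' Averages each ROI's time-averaged responses over trials per direction
#' (trial means, the default convention) and runs [dsi_osi()].
#'
#' @param rts A `roi_trace_set` whose stimuli are 8-direction gratings.
#' @param window Averaging window, see [time_avg_response()].
#' @param ... Passed to [dsi_osi()].
#' @return Named list of `direction_tuning`, one per ROI.
#' @export
roi_direction_tuning <- function(rts, window = "full", ...) {
  resp <- roi_responses(rts, window)
  out <- lapply(split(resp, resp$roi_id), function(d) {
    agg <- stats::aggregate(response ~ direction_deg, d, mean)
    agg <- agg[order(agg$direction_deg), ]
    dsi_osi(agg$response, agg$direction_deg, ...)
  })
  out[rts$roi_ids]
}
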