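#' Charge transfer of a voltage-clamp sweep
#'
#' Subtracts the mean baseline current (recorded immediately before the
#' stimulus) from the current in the response window and integrates the
#' remainder by the trapezoidal rule. pA integrated over seconds is reported
#' as pC; the sign of the current is preserved (outward positive at +20 mV,
#' inward negative at -65 mV).
#'
#' The baseline mean uses the half-open window `[from, to)`; the integral
#' spans the closed response window so that adjoining windows tile exactly
#' (charge is additive over `[a, b]` + `[b, c]`).
#'
#' @param trace A current [sweep_trace()].
#' @param baseline_window_s Length-2 numeric, baseline interval (s);
#'   defaults to the 0.5 s immediately before stimulus onset.
#' @param response_window_s Length-2 numeric, response interval (s);
#'   defaults to the stimulus window.
#' @return Charge (pC), signed.
#' @export
charge_transfer <- function(trace,
                            baseline_window_s = c(trace$t_stim_on_s - 0.5,
                                                  trace$t_stim_on_s),
                            response_window_s = c(trace$t_stim_on_s,
                                                  trace$t_stim_off_s)) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (trace$channel_kind != "current")
    stop("charge_transfer requires a current trace, got ", trace$channel_kind)
  if (baseline_window_s[1] >= response_window_s[1] + 1e-12 ||
      baseline_window_s[2] > response_window_s[1] + 1e-9)
    stop("baseline window must precede the response window")
  base_idx <- .window_idx(trace, baseline_window_s[1], baseline_window_s[2])
  resp_idx <- .window_idx(trace, response_window_s[1], response_window_s[2],
                          closed_right = TRUE)
  baseline <- mean(trace$values[base_idx])
  t <- sweep_times(trace)[resp_idx]
  pracma::trapz(t, trace$values[resp_idx] - baseline)
}

#' Count spikes in a window
#'
#' Half-open convention: a spike exactly at the window end is excluded.
#'
#' @param train A [spike_train()].
#' @param window_s Length-2 numeric `c(from, to)` (s).
#' @return Integer spike count.
#' @export
spike_count <- function(train, window_s) {
  stopifnot(inherits(train, "spike_train"))
  if (window_s[1] >= window_s[2]) stop("inverted window")
  if (window_s[1] < 0 || window_s[2] > train$sweep_length_s + 1e-9)
    stop("window outside sweep")
  sum(train$spike_times_s >= window_s[1] & train$spike_times_s < window_s[2])
}

#' Build a tuning curve from per-speed trial responses
#'
#' @param responses Named list: names are stimulus values (speeds in um/s,
#'   diameters in um, or directions in deg), elements are numeric vectors of
#'   per-trial responses. Unequal trial counts are allowed; missing trials
#'   are never imputed.
#' @param units Response units label (`"spikes"`, `"pC"`, `"dF/F"`, `"pA"`).
#' @return An object of class `tuning_curve`: `x` (sorted ascending),
#'   `per_trial` (trials x points matrix, `NA`-padded), `mean`, `sem`
#'   (sample SD / sqrt(trials); 0 where a single trial), `units`,
#'   `normalization = "raw"`, `measured_mask` (all `TRUE` for a single
#'   cell).
#' @export
build_tuning_curve <- function(responses, units = "pC") {
  if (length(responses) < 2)
    stop("insufficient data: need responses at >= 2 distinct stimulus values")
  x <- as.numeric(names(responses))
  if (any(is.na(x))) stop("response names must be numeric stimulus values")
  ord <- order(x)
  x <- x[ord]; responses <- responses[ord]
  if (any(duplicated(x))) stop("duplicate stimulus values")
  max_tr <- max(lengths(responses))
  per_trial <- sapply(responses, function(v) c(v, rep(NA_real_, max_tr - length(v))))
  per_trial <- matrix(per_trial, nrow = max_tr)
  m <- apply(per_trial, 2, mean, na.rm = TRUE)
  sem <- apply(per_trial, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  })
  new_tuning_curve(x, per_trial, m, sem, units, "raw", rep(TRUE, length(x)))
}

new_tuning_curve <- function(x, per_trial, mean, sem, units, normalization,
                             measured_mask) {
  stopifnot(!is.unsorted(x, strictly = TRUE))
  structure(list(x = x, per_trial = per_trial, mean = mean, sem = sem,
                 units = units, normalization = normalization,
                 measured_mask = measured_mask),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %d points, units %s, normalization %s\n",
              length(x$x), x$units, x$normalization))
  print(data.frame(x = x$x, mean = signif(x$mean, 4), sem = signif(x$sem, 3),
                   measured = x$measured_mask), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, log = "x", type = "b", ...) {
  graphics::plot(x$x, x$mean, log = log, type = type,
                 xlab = "stimulus", ylab = x$units, ...)
  graphics::arrows(x$x, x$mean - x$sem, x$x, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Optimal stimulus value of a tuning curve
#'
#' The x at which the trial-averaged curve is maximal. Exact ties are broken
#' toward the slowest (smallest) x, a conservative convention for a
#' slow-tuned cell class. An all-zero curve triggers a degenerate-curve
#' warning and returns the smallest x.
#'
#' @param curve A `tuning_curve`.
#' @return The optimal x (same units as `curve$x`).
#' @export
optimal_speed <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  m <- abs(curve$mean)
  if (all(m == 0)) {
    warning("degenerate all-zero tuning curve; returning slowest x")
    return(curve$x[1])
  }
  curve$x[which.max(m)]   # which.max takes the first (slowest) of exact ties
}

#' Half-maximum cutoff speed of a tuning curve
#'
#' Starting from the optimal point, scans toward faster speeds for the first
#' downward crossing of half the maximal response on the descending branch,
#' locating it by linear interpolation between data points. If the curve
#' never falls to half its maximum within the tested range the cutoff is
#' beyond range and `Inf` is returned.
#'
#' @param curve A `tuning_curve`.
#' @return Interpolated crossing x, or `Inf` if beyond the tested range.
#' @export
half_max_speed <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  m <- abs(curve$mean)
  if (all(m == 0)) return(Inf)
  i0 <- which.max(m)
  half <- m[i0] / 2
  if (i0 == length(m)) return(Inf)
  for (j in seq(i0 + 1, length(m))) {
    if (m[j] <= half) {
      x0 <- curve$x[j - 1]; x1 <- curve$x[j]
      y0 <- m[j - 1]; y1 <- m[j]
      return(x0 + (x1 - x0) * (y0 - half) / (y0 - y1))
    }
  }
  Inf
}

#' Normalize a tuning curve
#'
#' `self_max` divides by the curve's own maximum (mean over trials), the
#' convention for pooling cells recorded without drugs; `control_max`
#' divides by the maximum of a reference (control-condition) curve from the
#' same cell, the convention for drug/CNO comparisons.
#'
#' @param curve A `tuning_curve`.
#' @param mode `"self_max"` or `"control_max"`.
#' @param reference Reference `tuning_curve`; required for `control_max`.
#' @return A normalized `tuning_curve` (per-trial values scaled too).
#' @export
normalize_curve <- function(curve, mode = c("self_max", "control_max"),
                            reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "tuning_curve"))
  denom <- if (mode == "self_max") max(abs(curve$mean)) else {
    if (is.null(reference)) stop("control_max normalization requires a reference curve")
    max(abs(reference$mean))
  }
  if (!is.finite(denom) || denom <= 0)
    stop("cannot normalize: reference maximum is zero")
  new_tuning_curve(curve$x, curve$per_trial / denom, curve$mean / denom,
                   curve$sem / denom, curve$units, mode, curve$measured_mask)
}

#' Average tuning curves over cells on a common interpolated grid
#'
#' The common grid is the union of all cells' x values restricted to the
#' range every cell covers (interpolation only -- never extrapolation); each
#' cell's curve is linearly interpolated onto it, then averaged. `sem` is
#' over cells. `measured_mask` is `TRUE` at grid points where at least one
#' cell had a real measured point.
#'
#' @param curves List of >= 2 `tuning_curve`s with consistent normalization.
#' @return A population `tuning_curve` (`per_trial` holds the cells x grid
#'   matrix of interpolated values).
#' @export
population_average <- function(curves) {
  if (length(curves) < 2) stop("need >= 2 curves")
  norms <- unique(vapply(curves, function(c) c$normalization, ""))
  if (length(norms) > 1)
    stop("curves have mixed normalization: ", paste(norms, collapse = ", "))
  lo <- max(vapply(curves, function(c) min(c$x), 0))
  hi <- min(vapply(curves, function(c) max(c$x), 0))
  if (lo > hi) stop("no overlap between the cells' stimulus ranges")
  grid <- sort(unique(unlist(lapply(curves, function(c) c$x))))
  grid <- grid[grid >= lo - 1e-9 & grid <= hi + 1e-9]
  interp <- t(vapply(curves, function(c)
    stats::approx(c$x, c$mean, xout = grid, ties = "ordered")$y,
    numeric(length(grid))))
  measured <- Reduce(`|`, lapply(curves, function(c) grid %in% c$x))
  m <- colMeans(interp)
  sem <- apply(interp, 2, stats::sd) / sqrt(length(curves))
  new_tuning_curve(grid, interp, m, sem, curves[[1]]$units, norms, measured)
}

#' Shift of the responsive speed range between conditions
#'
#' Both curves must be normalized to the control maximum. The cutoff of each
#' curve is its descending crossing of response = 0.5 ([half_max_speed()] on
#' the control-normalized curves); the shift is the treated crossing minus
#' the control crossing (positive = range extension toward faster speeds).
#'
#' @param ctrl,treated Control and treated `tuning_curve`s, both
#'   `control_max`-normalized (control max = 1).
#' @return Shift (um/s); `Inf` with a warning if the treated curve never
#'   descends to 0.5 within range, `-Inf` if only the control fails to.
#' @export
speed_range_shift <- function(ctrl, treated) {
  for (c in list(ctrl, treated))
    if (c$normalization == "raw")
      stop("curves must be normalized to the control maximum first")
  c_cross <- .cross_down(ctrl, 0.5)
  t_cross <- .cross_down(treated, 0.5)
  if (!is.finite(c_cross) || !is.finite(t_cross))
    warning("half-maximum crossing beyond tested range; shift is partial")
  t_cross - c_cross
}

# first downward crossing of |mean| = level after the global maximum
.cross_down <- function(curve, level) {
  m <- abs(curve$mean)
  i0 <- which.max(m)
  if (m[i0] < level || i0 == length(m)) return(Inf)
  for (j in seq(i0 + 1, length(m))) {
    if (m[j] <= level) {
      x0 <- curve$x[j - 1]; x1 <- curve$x[j]
      return(x0 + (x1 - x0) * (m[j - 1] - level) / (m[j - 1] - m[j]))
    }
  }
  Inf
}

#' Pointwise excitation/inhibition ratio
#'
#' Interpolates both absolute charge-transfer curves onto their common grid
#' and returns the pointwise ratio `|E| / |I|`. Points where the inhibitory
#' magnitude falls below `floor_pC` are masked (`NA`) rather than reported
#' as unbounded ratios. Normalized inputs are rejected: the ratio is only
#' meaningful in absolute charge units.
#'
#' @param exc,inh Raw (un-normalized) charge `tuning_curve`s from one cell.
#' @param floor_pC Inhibition magnitude floor (pC), default 1.
#' @return A `tuning_curve` of E/I ratios (units `"ratio"`); masked points
#'   have `NA` mean and `measured_mask = FALSE`.
#' @export
ei_ratio <- function(exc, inh, floor_pC = 1) {
  if (exc$normalization != "raw" || inh$normalization != "raw")
    stop("E/I ratio requires raw absolute charge curves, not normalized ones")
  if (exc$units != inh$units)
    stop("unit mismatch: ", exc$units, " vs ", inh$units)
  lo <- max(min(exc$x), min(inh$x)); hi <- min(max(exc$x), max(inh$x))
  if (lo > hi) stop("no overlap between curves")
  grid <- sort(unique(c(exc$x, inh$x)))
  grid <- grid[grid >= lo & grid <= hi]
  e <- abs(stats::approx(exc$x, exc$mean, xout = grid, ties = "ordered")$y)
  i <- abs(stats::approx(inh$x, inh$mean, xout = grid, ties = "ordered")$y)
  ratio <- ifelse(i >= floor_pC, e / i, NA_real_)
  new_tuning_curve(grid, matrix(ratio, nrow = 1), ratio,
                   rep(0, length(grid)), "ratio", "raw", !is.na(ratio))
}

#' Interpolated peak location of a log-Gaussian-shaped tuning curve
#'
#' Recovers the underlying tuning peak more finely than the stimulus grid by
#' fitting a parabola to `ln(response)` against `ln(x)` over the points near
#' the maximum (a log-Gaussian is exactly quadratic on those axes). Used to
#' check generator parameter recovery.
#'
#' @param curve A `tuning_curve` with positive responses near its maximum.
#' @param frac Points with mean >= `frac * max` enter the fit (default 0.2).
#' @return List with `peak_x` (vertex) and `log_width` (from curvature);
#'   falls back to the grid argmax when fewer than 3 points qualify.
#' @export
tuning_peak_fit <- function(curve, frac = 0.2) {
  m <- abs(curve$mean)
  keep <- which(m >= frac * max(m) & m > 0)
  if (length(keep) < 3)
    return(list(peak_x = optimal_speed(curve), log_width = NA_real_))
  lx <- log(curve$x[keep]); ly <- log(m[keep])
  fit <- stats::lm(ly ~ lx + I(lx^2))
  a <- stats::coef(fit)[[3]]; b <- stats::coef(fit)[[2]]
  if (!is.finite(a) || a >= 0)
    return(list(peak_x = optimal_speed(curve), log_width = NA_real_))
  list(peak_x = exp(-b / (2 * a)), log_width = sqrt(-1 / (2 * a)))
}
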