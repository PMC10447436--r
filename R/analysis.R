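#' Tuning curve from a simulated or recorded speed series
#'
#' Applies the response definition of the speed-tuning analyses to every
#' trial of a speed series: total spike count over the stimulus for spike
#' trains, baseline-subtracted charge-transfer magnitude (pC) for
#' voltage-clamp sweeps (0.5 s baseline immediately before the stimulus).
#'
#' @param series As returned by [simulate_speed_series()] or
#'   [read_speed_series()].
#' @return A raw `tuning_curve` (units `"spikes"` or `"pC"`).
#' @export
speed_tuning_from_series <- function(series) {
  responses <- list()
  units <- NULL
  for (sp in series) {
    v <- as.character(sp$stimulus$speed_um_s)
    responses[[v]] <- vapply(sp$trials, function(tr) {
      if (inherits(tr, "spike_train")) {
        units <<- "spikes"
        spike_count(tr, c(tr$t_stim_on_s, tr$t_stim_off_s))
      } else {
        units <<- "pC"
        abs(charge_transfer(tr))
      }
    }, 0)
  }
  build_tuning_curve(responses, units = units)
}

#' Simulate a population of cells and extract their tuning curves
#'
#' One cell per seed offset; each cell is an independent speed series drawn
#' from the same generator parameters.
#'
#' @param params A [sim_params()].
#' @param n_cells Number of cells.
#' @param modality,condition Passed to [simulate_speed_series()].
#' @param speeds Speed grid (default [default_speed_grid()]).
#' @param n_trials Trials per speed.
#' @param seed Base seed; cell i uses `seed + i`.
#' @return List of raw `tuning_curve`s, one per cell.
#' @export
simulate_population_curves <- function(params, n_cells,
                                       modality = "spikes",
                                       condition = "control",
                                       speeds = default_speed_grid(),
                                       n_trials = 3, seed = params$seed) {
  lapply(seq_len(n_cells), function(i) {
    series <- simulate_speed_series(params, speeds, modality, condition,
                                    n_trials = n_trials, seed = seed + i)
    speed_tuning_from_series(series)
  })
}

#' Compare control and treated speed tuning in a cell population
#'
#' For each cell both curves are normalized by the cell's control maximum,
#' then averaged over cells; the effect at the maximum is tested with a
#' paired one-sided t-test on per-cell responses at the control-optimal
#' speed, and the speed-range shift is measured at the normalized 0.5 line.
#'
#' @param ctrl_curves,treated_curves Paired lists of raw `tuning_curve`s
#'   (same cells, same order).
#' @param tail Tail for the paired test (default `"one_sided_greater"`:
#'   control > treated).
#' @return An object of class `condition_comparison`: population `control`
#'   and `treated` curves (control-max normalized), `paired_cells`,
#'   `effect_at_max` (fractional change at the control maximum),
#'   `test` (a `test_result`), `shift_at_half` (um/s).
#' @export
compare_conditions <- function(ctrl_curves, treated_curves,
                               tail = "one_sided_greater") {
  n <- length(ctrl_curves)
  if (n < 1 || n != length(treated_curves))
    stop("need paired control/treated curves")
  ctrl_n <- vector("list", n); trt_n <- vector("list", n)
  at_max_c <- numeric(n); at_max_t <- numeric(n)
  for (i in seq_len(n)) {
    ctrl_n[[i]] <- normalize_curve(ctrl_curves[[i]], "control_max",
                                   reference = ctrl_curves[[i]])
    trt_n[[i]] <- normalize_curve(treated_curves[[i]], "control_max",
                                  reference = ctrl_curves[[i]])
    i_max <- which.max(abs(ctrl_curves[[i]]$mean))
    at_max_c[i] <- abs(ctrl_curves[[i]]$mean[i_max])
    x_max <- ctrl_curves[[i]]$x[i_max]
    at_max_t[i] <- abs(stats::approx(treated_curves[[i]]$x,
                                     treated_curves[[i]]$mean,
                                     xout = x_max, ties = "ordered")$y)
  }
  pop_c <- if (n >= 2) population_average(ctrl_n) else ctrl_n[[1]]
  pop_t <- if (n >= 2) population_average(trt_n) else trt_n[[1]]
  test <- if (n >= 2) paired_t(at_max_c, at_max_t, tail) else NULL
  structure(list(
    control = pop_c, treated = pop_t, paired_cells = n,
    effect_at_max = mean(at_max_t / at_max_c) - 1,
    test = test,
    shift_at_half = speed_range_shift(pop_c, pop_t)),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %d paired cells; effect at max %+.1f%%",
              x$paired_cells, 100 * x$effect_at_max))
  if (!is.null(x$test)) cat(sprintf(", p = %.3g %s", x$test$p_value, x$test$stars))
  cat(sprintf("; shift at half-max %.3g um/s\n", x$shift_at_half))
  invisible(x)
}
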