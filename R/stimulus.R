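#' Visual or optogenetic stimulus description
#'
#' One stimulus condition as projected on the retina. Drifting gratings are
#' parameterized by spatial cycle, retinal drift speed and direction; spots
#' and masked gratings additionally by aperture diameter; optogenetic pulses
#' by duration only. Angles are in degrees, 0 = nasal, counterclockwise.
#'
#' @param kind One of `"grating"`, `"spot"`, `"masked_grating"`, `"opto_pulse"`.
#' @param cycle_um Grating spatial period (um). Default 377 um.
#' @param contrast Michelson contrast in `[0, 1]`. Default 0.95.
#' @param speed_um_s Retinal drift speed (um/s), >= 0.
#' @param direction_deg Drift direction (deg).
#' @param diameter_um Aperture diameter (um); `Inf` = full field.
#' @param duration_s Stimulus duration (s). Default 5 s.
#' @param interstim_s Inter-stimulus interval (s). Default 3 s.
#' @param n_trials Repetitions. Default 3.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("grating", "spot", "masked_grating", "opto_pulse"),
                          cycle_um = 377, contrast = 0.95, speed_um_s = 0,
                          direction_deg = 0, diameter_um = Inf,
                          duration_s = 5, interstim_s = 3, n_trials = 3) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (speed_um_s < 0) stop("speed_um_s must be >= 0")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (kind != "opto_pulse" && cycle_um <= 0 && speed_um_s > 0)
    stop("cycle_um must be > 0 for a drifting stimulus")
  structure(
    list(kind = kind, cycle_um = cycle_um, contrast = contrast,
         speed_um_s = speed_um_s, direction_deg = direction_deg %% 360,
         diameter_um = diameter_um, duration_s = duration_s,
         interstim_s = interstim_s, n_trials = n_trials),
    class = "stimulus_spec")
}

#' Temporal frequency of a drifting grating
#' @param stim A [stimulus_spec()].
#' @return Cycles per second (Hz), `speed_um_s / cycle_um`.
#' @export
temporal_frequency <- function(stim) {
  stopifnot(inherits(stim, "stimulus_spec"))
  stim$speed_um_s / stim$cycle_um
}

#' Convert retinal speed to angular velocity
#'
#' Uses a configurable retinal magnification factor; the mouse-eye default of
#' 30 um per degree of visual angle maps 150 um/s to 5 deg/s.
#'
#' @param speed_um_s Retinal speed(s) (um/s).
#' @param um_per_deg Retinal magnification (um per degree). Default 30.
#' @return Angular velocity (deg/s).
#' @export
speed_to_deg_s <- function(speed_um_s, um_per_deg = 30) speed_um_s / um_per_deg

#' Default grating speed grid (um/s)
#'
#' Seven speeds spanning 76 to 2900 um/s, the range over which drifting
#' gratings are tested; spacing is roughly octave below 1200 um/s.
#' @return Numeric vector of speeds.
#' @export
default_speed_grid <- function() c(76, 150, 300, 600, 1200, 1910, 2900)
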