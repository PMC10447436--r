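#' Tilted fiducial-band geometry for a reconstruction volume
#'
#' The two starburst (ChAT) plexuses are modeled as parallel planes
#' `z = z0 + tilt_x * x + tilt_y * y` (OFF band) and the same plane offset by
#' `band_gap_um` (ON band), emulating the tilt of the tissue in an SBEM
#' block. Used both by the synapse-table generator and as a ground-truth
#' [band_model()] for depth normalization.
#'
#' @param z0_um OFF-band depth at the volume origin (um).
#' @param tilt_x,tilt_y Plane slopes (um depth per um lateral).
#' @param band_gap_um Depth separation between OFF and ON bands (um).
#' @param extent_um Lateral extent of the volume (um).
#' @return A list of class `band_geometry`.
#' @export
band_geometry <- function(z0_um = 20, tilt_x = 0.05, tilt_y = 0.03,
                          band_gap_um = 12, extent_um = c(210, 260)) {
  if (band_gap_um <= 0) stop("band_gap_um must be > 0")
  structure(list(z0_um = z0_um, tilt_x = tilt_x, tilt_y = tilt_y,
                 band_gap_um = band_gap_um, extent_um = extent_um),
            class = "band_geometry")
}

.band_z <- function(geom, x, y, which = c("off", "on")) {
  which <- match.arg(which)
  z <- geom$z0_um + geom$tilt_x * x + geom$tilt_y * y
  if (which == "on") z <- z + geom$band_gap_um
  z
}

#' Simulate an annotated synapse table
#'
#' Draws, for each presynaptic type, the requested number of synapse
#' annotations at uniform lateral positions in the volume, with normalized
#' IPL depths from type-specific Gaussian distributions (OFF SAC plexus = 0,
#' ON SAC plexus = 1) converted to raw depths through the tilted band
#' geometry. Default depth centers place SAC and widefield inputs at the ON
#' plexus and VGluT3 inputs mid-way between the bands, as in the
#' reconstructed stratification profiles.
#'
#' @param counts_by_type Named integer vector, e.g.
#'   `c(SAC = 363, WF = 30, VGluT3 = 40, other = 5, unidentified = 22)`.
#' @param geom A [band_geometry()].
#' @param depth_centers,depth_sds Named numeric vectors of normalized-depth
#'   means/SDs per type; types missing from them use `0.9` / `0.2`.
#' @param seed Integer seed.
#' @return A `data.frame` of class `synapse_table` with columns
#'   `synapse_id`, `presyn_cell_id`, `presyn_type`, `x_um`, `y_um`, `z_um`,
#'   `depth_raw_um`, `depth_norm`.
#' @export
simulate_synapse_table <- function(counts_by_type, geom = band_geometry(),
                                   depth_centers = c(SAC = 1.0, WF = 1.05,
                                                     VGluT3 = 0.65, other = 0.8,
                                                     unidentified = 0.9),
                                   depth_sds = c(SAC = 0.10, WF = 0.15,
                                                 VGluT3 = 0.12, other = 0.2,
                                                 unidentified = 0.3),
                                   seed = 1L) {
  if (is.null(names(counts_by_type)) || any(!nzchar(names(counts_by_type))))
    stop("counts_by_type must be a named vector")
  counts_by_type <- stats::setNames(as.integer(counts_by_type),
                                    names(counts_by_type))
  stopifnot(all(counts_by_type >= 0))
  types <- rep(names(counts_by_type), counts_by_type)
  n <- length(types)
  if (n == 0) {
    out <- data.frame(synapse_id = character(0), presyn_cell_id = character(0),
                      presyn_type = character(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      depth_raw_um = numeric(0), depth_norm = numeric(0))
    class(out) <- c("synapse_table", "data.frame")
    return(out)
  }
  withr::with_seed(seed, {
    x <- stats::runif(n, 0, geom$extent_um[1])
    y <- stats::runif(n, 0, geom$extent_um[2])
    mu <- ifelse(types %in% names(depth_centers), depth_centers[types], 0.9)
    sd <- ifelse(types %in% names(depth_sds), depth_sds[types], 0.2)
    dn <- stats::rnorm(n, mu, sd)
    z_off <- .band_z(geom, x, y, "off")
    z <- z_off + dn * geom$band_gap_um
    # cycle synapses over a plausible number of presynaptic cells per type
    # (VGluT3: 40 synapses from 16 cells)
    cell <- character(n)
    for (ty in unique(types)) {
      sel <- which(types == ty)
      nc <- if (ty == "VGluT3") min(16L, length(sel)) else max(1L, round(length(sel) / 10))
      cell[sel] <- paste0(ty, "_", sprintf("%02d", 1 + (seq_along(sel) - 1) %% nc))
    }
    out <- data.frame(
      synapse_id = sprintf("syn%04d", seq_len(n)),
      presyn_cell_id = cell, presyn_type = types,
      x_um = x, y_um = y, z_um = z,
      depth_raw_um = z, depth_norm = NA_real_)
    class(out) <- c("synapse_table", "data.frame")
    out
  })
}

#' Default synapse counts of the reconstructed ON DSGC
#'
#' Per-type counts of the non-ribbon (amacrine-cell) synaptic contacts onto
#' the reconstructed ON DSGC: 363 from starburst amacrine cells, 30 from
#' widefield cells, 40 from VGluT3 cells, 5 from other identified types
#' (438 identified in total) plus 22 from unidentifiable fragments
#' (460 overall).
#' @return Named integer vector.
#' @export
reference_synapse_counts <- function() {
  c(SAC = 363L, WF = 30L, VGluT3 = 40L, other = 5L, unidentified = 22L)
}
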