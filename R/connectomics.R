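#' Tally synapses by presynaptic type
#'
#' Counts and percentages of annotated synapses per presynaptic cell type.
#' With `denominator = "identified"` (the reporting convention for the
#' reconstructed ON DSGC) rows labelled `"unidentified"` are excluded from
#' the percentage denominator; `"all"` uses every row. Percentages are kept
#' at full precision with rounded integer companions; they sum to 100
#' before rounding.
#'
#' @param table A `synapse_table` (or data.frame with a `presyn_type`
#'   column), nonempty.
#' @param denominator `"identified"` or `"all"`.
#' @return data.frame with `presyn_type`, `count`, `pct`, `pct_rounded`,
#'   plus attributes `denominator` and `n_denominator`.
#' @export
tally_by_type <- function(table, denominator = c("identified", "all")) {
  denominator <- match.arg(denominator)
  if (!nrow(table)) stop("empty synapse table")
  counts <- table(factor(table$presyn_type))
  denom_types <- if (denominator == "identified")
    setdiff(names(counts), "unidentified") else names(counts)
  n_denom <- sum(counts[denom_types])
  out <- data.frame(presyn_type = names(counts),
                    count = as.integer(counts), row.names = NULL)
  out$pct <- ifelse(out$presyn_type %in% denom_types,
                    100 * out$count / n_denom, NA_real_)
  out$pct_rounded <- round(out$pct)
  out <- out[order(-out$count), ]
  rownames(out) <- NULL
  attr(out, "denominator") <- denominator
  attr(out, "n_denominator") <- n_denom
  out
}

#' Fiducial band model from annotated band nodes
#'
#' Fits the OFF and ON starburst (ChAT) plexuses as least-squares polynomial
#' surfaces `z = f(x, y)` of low order, from user-supplied band node
#' annotations, to correct for the tilt and curvature of the tissue block.
#'
#' @param off_nodes,on_nodes data.frames with columns `x`, `y`, `z` (um) of
#'   annotated nodes on each plexus.
#' @param degree Polynomial degree (1 = plane, 2 adds curvature; default 1).
#' @return An object of class `band_model` with `predict_off(x, y)` /
#'   `predict_on(x, y)` closures.
#' @export
fit_band_model <- function(off_nodes, on_nodes, degree = 1) {
  fit_one <- function(nodes) {
    stopifnot(all(c("x", "y", "z") %in% names(nodes)))
    form <- if (degree >= 2) z ~ x + y + I(x^2) + I(y^2) + I(x * y) else z ~ x + y
    fit <- stats::lm(form, data = nodes)
    function(x, y) as.numeric(stats::predict(fit, data.frame(x = x, y = y)))
  }
  f_off <- fit_one(off_nodes); f_on <- fit_one(on_nodes)
  structure(list(predict_off = f_off, predict_on = f_on, degree = degree),
            class = "band_model")
}

#' Band model from a known (simulated) band geometry
#' @param geom A [band_geometry()].
#' @return A `band_model` with exact plane surfaces.
#' @export
band_model_from_geometry <- function(geom) {
  stopifnot(inherits(geom, "band_geometry"))
  structure(list(
    predict_off = function(x, y) .band_z(geom, x, y, "off"),
    predict_on = function(x, y) .band_z(geom, x, y, "on"),
    degree = 1), class = "band_model")
}

#' Normalize synapse depths to the SAC plexuses
#'
#' Converts raw depths to the fiducial coordinate in which the OFF SAC
#' plexus maps to 0 and the ON SAC plexus to 1 at every lateral position:
#' `depth_norm = (z - z_off(x, y)) / (z_on(x, y) - z_off(x, y))`, with
#' linear extrapolation outside the bands. This removes the tilt and
#' curvature of the tissue in the block.
#'
#' @param table A `synapse_table` with `x_um`, `y_um`, `z_um`.
#' @param bands A `band_model`.
#' @return The table with `depth_norm` filled.
#' @export
normalize_depth <- function(table, bands) {
  stopifnot(inherits(bands, "band_model"))
  if (!nrow(table)) return(table)
  z_off <- bands$predict_off(table$x_um, table$y_um)
  z_on <- bands$predict_on(table$x_um, table$y_um)
  gap <- z_on - z_off
  if (any(abs(gap) < 1e-9))
    stop("degenerate band geometry: ON and OFF surfaces intersect")
  table$depth_norm <- (table$z_um - z_off) / gap
  table
}

#' Stratification histogram per presynaptic type
#'
#' @param table A `synapse_table` with `depth_norm` filled.
#' @param bin_width Bin width in normalized-depth units (> 0), default 0.1.
#' @return data.frame with `presyn_type`, `bin_lo`, `bin_hi` (half-open
#'   bins `[lo, hi)`), `count`.
#' @export
stratification_profile <- function(table, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!nrow(table))
    return(data.frame(presyn_type = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), count = integer(0)))
  if (any(is.na(table$depth_norm)))
    stop("depth_norm missing; run normalize_depth() first")
  lo_all <- floor(min(table$depth_norm) / bin_width) * bin_width
  hi_all <- floor(max(table$depth_norm) / bin_width) * bin_width + bin_width
  edges <- seq(lo_all, hi_all, by = bin_width)
  out <- do.call(rbind, lapply(split(table, table$presyn_type), function(d) {
    idx <- findInterval(d$depth_norm, edges, rightmost.closed = FALSE)
    cnt <- tabulate(idx, nbins = length(edges) - 1)
    data.frame(presyn_type = d$presyn_type[1],
               bin_lo = utils::head(edges, -1), bin_hi = edges[-1],
               count = cnt)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write synapse tables as CSV
#'
#' Column layout: `synapse_id, presyn_cell_id, presyn_type, x_um, y_um,
#' z_um, depth_raw_um, depth_norm`. A column mapping can rename input
#' columns.
#'
#' @param path CSV path.
#' @param table A `synapse_table`.
#' @param col_map Optional named character vector `c(ours = theirs)` mapping
#'   expected column names to those present in the file.
#' @return `read_synapse_table()` returns a `synapse_table`;
#'   `write_synapse_table()` returns `path` invisibly.
#' @export
read_synapse_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      theirs <- col_map[[ours]]
      if (theirs %in% names(df)) names(df)[names(df) == theirs] <- ours
    }
  }
  need <- c("synapse_id", "presyn_type", "x_um", "y_um", "z_um")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$synapse_id)) stop("synapse_id values must be unique")
  if (is.null(df$depth_norm)) df$depth_norm <- NA_real_
  if (is.null(df$depth_raw_um)) df$depth_raw_um <- df$z_um
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' @rdname read_synapse_table
#' @export
write_synapse_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
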