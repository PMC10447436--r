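#' Write / read a simulated speed series as a plain-text container
#'
#' One directory per call: `manifest.json` describes every group (cell,
#' condition, speed, trial, stimulus fields, sampling) and each sweep or
#' spike train lives in its own single-column CSV. The same layout holds
#' currents and spike trains.
#'
#' @param series Output of [simulate_speed_series()].
#' @param dir Target directory (created if needed).
#' @param cell_id,condition Labels stored in the manifest.
#' @return `write_speed_series()` returns `dir` invisibly;
#'   `read_speed_series()` returns the series in the same shape
#'   [simulate_speed_series()] produces.
#' @export
write_speed_series <- function(series, dir, cell_id = "cell1",
                               condition = "control") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- list()
  gi <- 0
  for (sp in series) {
    for (k in seq_along(sp$trials)) {
      gi <- gi + 1
      tr <- sp$trials[[k]]
      file <- sprintf("group%04d.csv", gi)
      if (inherits(tr, "sweep_trace")) {
        utils::write.csv(data.frame(value = tr$values),
                         file.path(dir, file), row.names = FALSE)
        meta <- list(kind = "sweep", sample_rate_hz = tr$sample_rate_hz,
                     t_stim_on_s = tr$t_stim_on_s, t_stim_off_s = tr$t_stim_off_s,
                     holding_mV = tr$holding_mV, channel_kind = tr$channel_kind)
      } else {
        utils::write.csv(data.frame(spike_time_s = tr$spike_times_s),
                         file.path(dir, file), row.names = FALSE)
        meta <- list(kind = "spikes", sweep_length_s = tr$sweep_length_s,
                     t_stim_on_s = tr$t_stim_on_s, t_stim_off_s = tr$t_stim_off_s)
      }
      groups[[gi]] <- c(list(file = file, cell_id = cell_id,
                             condition = condition, trial = k,
                             stimulus = unclass(sp$stimulus)), meta)
    }
  }
  jsonlite::write_json(groups, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_speed_series
#' @export
read_speed_series <- function(dir) {
  groups <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = FALSE)
  by_speed <- split(groups, vapply(groups, function(g) g$stimulus$speed_um_s, 0))
  out <- lapply(by_speed, function(gs) {
    s <- gs[[1]]$stimulus
    diam <- if (is.null(s$diameter_um)) Inf else s$diameter_um
    stim <- stimulus_spec(s$kind, cycle_um = s$cycle_um, contrast = s$contrast,
                          speed_um_s = s$speed_um_s, direction_deg = s$direction_deg,
                          diameter_um = diam, duration_s = s$duration_s,
                          interstim_s = s$interstim_s, n_trials = s$n_trials)
    trials <- lapply(gs, function(g) {
      df <- utils::read.csv(file.path(dir, g$file))
      if (g$kind == "sweep") {
        sweep_trace(df$value, g$sample_rate_hz, g$t_stim_on_s, g$t_stim_off_s,
                    holding_mV = g$holding_mV, channel_kind = g$channel_kind)
      } else {
        spike_train(df$spike_time_s, g$sweep_length_s, g$t_stim_on_s,
                    g$t_stim_off_s)
      }
    })
    list(stimulus = stim, trials = trials)
  })
  ord <- order(as.numeric(names(out)))
  unname(out[ord])
}

#' Write / read a ROI trace set as a plain-text container
#'
#' `traces.csv` holds the frames x ROIs fluorescence matrix,
#' `stimulus_table.csv` the presentation table, `meta.json` the frame rate
#' and FOV id.
#'
#' @param rts A `roi_trace_set`.
#' @param dir Target directory.
#' @return `write_roi_trace_set()` returns `dir` invisibly;
#'   `read_roi_trace_set()` a `roi_trace_set`.
#' @export
write_roi_trace_set <- function(rts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- sapply(rts$traces, function(tr) tr$values)
  colnames(mat) <- rts$roi_ids
  utils::write.csv(as.data.frame(mat), file.path(dir, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(rts$stimulus_table, file.path(dir, "stimulus_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_rate_hz = rts$frame_rate_hz,
                            fov_id = rts$fov_id,
                            t_first_on_s = rts$traces[[1]]$t_stim_on_s,
                            t_last_off_s = rts$traces[[1]]$t_stim_off_s),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_roi_trace_set
#' @export
read_roi_trace_set <- function(dir) {
  mat <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  st <- utils::read.csv(file.path(dir, "stimulus_table.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  traces <- lapply(seq_len(ncol(mat)), function(j)
    sweep_trace(mat[[j]], meta$frame_rate_hz, meta$t_first_on_s,
                meta$t_last_off_s, channel_kind = "fluorescence"))
  structure(list(roi_ids = colnames(mat), traces = traces,
                 stimulus_table = st, frame_rate_hz = meta$frame_rate_hz,
                 fov_id = meta$fov_id),
            class = "roi_trace_set")
}

#' Write a tuning summary CSV
#'
#' Long-format export (`cell_id`, `condition`, `x`, `mean`, `sem`,
#' `measured`) of one or more tuning curves.
#'
#' @param curves Named list of `tuning_curve` (names = `cell_id:condition`
#'   or plain cell ids).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_summary <- function(curves, path) {
  rows <- lapply(names(curves), function(nm) {
    c <- curves[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(cell_id = parts[1],
               condition = if (length(parts) > 1) parts[2] else "control",
               x = c$x, mean = c$mean, sem = c$sem, measured = c$measured_mask)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
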