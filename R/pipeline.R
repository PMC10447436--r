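#' Run a simulate-analyze-report pipeline from a configuration
#'
#' Executes the requested analyses end to end on synthetic data: generation
#' with the configured parameters, metric extraction, condition comparisons,
#' and a report bundle (`metrics.json`, per-analysis CSV tables and a log of
#' every configuration value and seed; no silent defaults). Identical
#' configuration and seed give byte-identical `metrics.json`.
#'
#' @param config A named list or path to a YAML/JSON file. Required keys:
#'   `analyses` (subset of `"ephys"`, `"opto"`, `"imaging"`,
#'   `"connectome"`) and `seed`. Optional: `n_cells` (default 5), `n_rois`
#'   (default 30), `condition` (treated condition for the ephys comparison,
#'   default `"cno"`), `params` (named [sim_params()] overrides).
#' @param out_dir Output directory.
#' @return Invisibly, the metrics list written to `metrics.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  missing <- setdiff(c("analyses", "seed"), names(config))
  if (length(missing))
    stop("config error: missing required field(s): ",
         paste(missing, collapse = ", "))
  known <- c("ephys", "opto", "imaging", "connectome")
  bad <- setdiff(config$analyses, known)
  if (length(bad))
    stop("config error: unknown analysis name(s): ", paste(bad, collapse = ", "))
  n_cells <- config$n_cells %||% 5
  n_rois <- config$n_rois %||% 30
  treated <- config$condition %||% "cno"
  params <- do.call(sim_params, c(config$params %||% list(),
                                  list(seed = as.integer(config$seed))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("seed: %d", params$seed)
  for (nm in names(config)) logf("config %s: %s", nm,
                                 paste(format(unlist(config[nm])), collapse = " "))
  metrics <- list(seed = params$seed)

  if ("ephys" %in% config$analyses) {
    logf("ephys: %d cells, treated condition %s", n_cells, treated)
    curves <- list()
    met <- list()
    for (mod in c("spikes", "exc_current", "inh_current")) {
      cc <- simulate_population_curves(params, n_cells, mod, "control",
                                       seed = params$seed + 1000 * match(mod,
                                         c("spikes", "exc_current", "inh_current")))
      pop <- population_average(lapply(cc, normalize_curve, mode = "self_max"))
      met[[mod]] <- list(
        optimal_speed_um_s = mean(vapply(cc, optimal_speed, 0)),
        half_max_speed_um_s = mean(vapply(cc, half_max_speed, 0)),
        peak_response = mean(vapply(cc, function(c) max(abs(c$mean)), 0)))
      curves[[paste0("population:", mod)]] <- pop
    }
    ctrl <- simulate_population_curves(params, n_cells, "inh_current",
                                       "control", seed = params$seed + 7)
    trt <- simulate_population_curves(params, n_cells, "inh_current",
                                      treated, seed = params$seed + 7)
    cmp <- compare_conditions(ctrl, trt)
    met$comparison <- list(condition = treated,
                           effect_at_max = cmp$effect_at_max,
                           p_value = cmp$test$p_value,
                           shift_at_half_um_s = cmp$shift_at_half)
    metrics$ephys <- met
    write_tuning_summary(curves, file.path(out_dir, "ephys_tuning.csv"))
  }

  if ("opto" %in% config$analyses) {
    logf("opto: %d cells", n_cells)
    conds <- c(control = "pr_block", glut_block = "glut_block",
               gly_block = "gly_block")
    summaries <- lapply(seq_len(n_cells), function(i) {
      trials <- lapply(conds, function(cd) lapply(1:3, function(k)
        smooth_trace(simulate_opto_trial(params, 1, 20, cd,
                                         seed = params$seed + 100 * i + k))))
      pharmacology_summary(trials, cell_id = sprintf("cell%02d", i))
    })
    peak <- mean(vapply(summaries, function(s)
      s$conditions$peak_pA[s$conditions$condition == "control"], 0))
    red_glut <- mean(vapply(summaries, function(s)
      s$conditions$reduction[s$conditions$condition == "glut_block"], 0))
    metrics$opto <- list(mean_ipsc_peak_pA = peak,
                         glut_block_reduction = red_glut,
                         excluded_cells = sum(vapply(summaries,
                                                     function(s) s$qc_exclude, TRUE)))
    tab <- do.call(rbind, lapply(summaries, function(s)
      cbind(cell_id = s$cell_id, s$conditions)))
    utils::write.csv(tab, file.path(out_dir, "opto_summary.csv"),
                     row.names = FALSE)
  }

  if ("imaging" %in% config$analyses) {
    logf("imaging: %d ROIs", n_rois)
    stimuli <- lapply(seq(0, 315, by = 45), function(d)
      stimulus_spec("grating", speed_um_s = 1520, direction_deg = d))
    rts <- simulate_roi_traces(params, stimuli, n_rois,
                               seed = params$seed + 41)
    tunings <- roi_direction_tuning(rts)
    fs <- fov_summary(tunings)
    metrics$imaging <- list(
      n_rois = fs$n_rois,
      mean_dsi = mean(vapply(tunings, function(t) t$dsi, 0), na.rm = TRUE),
      mean_osi = mean(vapply(tunings, function(t) t$osi, 0), na.rm = TRUE),
      pct_os = fs$classification$pct[fs$classification$class == "os"],
      pct_ds = fs$classification$pct[fs$classification$class == "ds"])
    utils::write.csv(fs$classification, file.path(out_dir, "imaging_classes.csv"),
                     row.names = FALSE)
  }

  if ("connectome" %in% config$analyses) {
    logf("connectome: reference counts")
    geom <- band_geometry()
    tab <- simulate_synapse_table(reference_synapse_counts(), geom,
                                  seed = params$seed + 91)
    tab <- normalize_depth(tab, band_model_from_geometry(geom))
    tally <- tally_by_type(tab, "identified")
    metrics$connectome <- list(
      n_synapses = nrow(tab),
      pct_sac = tally$pct[tally$presyn_type == "SAC"],
      pct_vglut3 = tally$pct[tally$presyn_type == "VGluT3"])
    utils::write.csv(tally, file.path(out_dir, "connectome_tally.csv"),
                     row.names = FALSE)
    write_synapse_table(tab, file.path(out_dir, "synapse_table.csv"))
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
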