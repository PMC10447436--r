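#!/usr/bin/env Rscript
# Generate the synthetic recording sets used by the downstream analysis
# scripts: speed series of spikes and synaptic currents, optogenetic pulse
# sweeps, ROI fluorescence traces, and the annotated synapse table. All
# outputs are plain-text containers under results/simulated/.
#
# The generator defaults encode the study conditions: spiking optimum
# 150 um/s, excitatory charge peaking at 710 um/s (490 pC), inhibitory at
# 1220 um/s (2200 pC), 57/43 glycine/GABA partition of inhibition, 43/26 pA
# optogenetic IPSC peaks for 1/0.1 s pulses, and calcium selectivity
# targets DSI 0.28 / OSI 0.38.

library(retinaspeed)

seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
p <- sim_params(seed = seed)

message("ephys speed series (example cell, three modalities) ...")
for (mod in c("spikes", "exc_current", "inh_current")) {
  series <- simulate_speed_series(p, default_speed_grid(), mod,
                                  seed = seed + match(mod, c("spikes", "exc_current", "inh_current")))
  write_speed_series(series, file.path(out, paste0("ephys_", mod)),
                     cell_id = "example_cell", condition = "control")
}

message("paired control/strychnine inhibitory series ...")
ctrl <- simulate_speed_series(p, default_speed_grid(), "inh_current",
                              "control", seed = seed + 11)
stry <- simulate_speed_series(p, default_speed_grid(), "inh_current",
                              "strychnine", seed = seed + 11)
write_speed_series(ctrl, file.path(out, "inh_control"), "cell_s1", "control")
write_speed_series(stry, file.path(out, "inh_strychnine"), "cell_s1", "strychnine")

message("ROI fluorescence traces (8-direction gratings, 30 ROIs) ...")
stims <- lapply(seq(0, 315, by = 45), function(d)
  stimulus_spec("grating", speed_um_s = 1520, direction_deg = d))
rts <- simulate_roi_traces(p, stims, n_rois = 30, seed = seed + 21)
write_roi_trace_set(rts, file.path(out, "roi_directions"))

message("synapse annotation table ...")
geom <- band_geometry()
tab <- simulate_synapse_table(reference_synapse_counts(), geom, seed = seed + 31)
write_synapse_table(tab, file.path(out, "synapse_table.csv"))

message("done; outputs under ", out)
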