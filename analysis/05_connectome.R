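#!/usr/bin/env Rscript
# Connectomic tabulation of the amacrine-cell synapses onto the
# reconstructed ON DSGC: per-type tallies over the identified and full
# denominators, depth normalization to the tilted SAC (ChAT) plexuses, and
# per-type stratification profiles.
#
# Findings: 83% of the 438 identified contacts come from starburst amacrine
# cells, 7% from widefield cells and 9% from VGluT3 cells (40 synapses, the
# only glycinergic type among the major inputs); depth normalization removes
# the block tilt, placing SAC/WF inputs at the ON plexus (depth 1) and
# VGluT3 inputs mid-way between the bands.

library(retinaspeed)

seed <- 1L
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geom <- band_geometry()           # tilted fiducial planes, 12 um band gap
tab <- simulate_synapse_table(reference_synapse_counts(), geom, seed = seed + 31)
tab <- normalize_depth(tab, band_model_from_geometry(geom))
write_synapse_table(tab, file.path(out, "synapse_table_normalized.csv"))

for (denom in c("identified", "all")) {
  tal <- tally_by_type(tab, denom)
  utils::write.csv(tal, file.path(out, paste0("synapse_tally_", denom, ".csv")),
                   row.names = FALSE)
  message("tally over ", denom, " synapses (n = ",
          attr(tal, "n_denominator"), "):")
  print(tal)
}

prof <- stratification_profile(tab, bin_width = 0.1)
utils::write.csv(prof, file.path(out, "stratification_profile.csv"),
                 row.names = FALSE)
peaks <- do.call(rbind, lapply(split(prof, prof$presyn_type), function(d)
  data.frame(presyn_type = d$presyn_type[1],
             modal_depth = d$bin_lo[which.max(d$count)])))
message("modal normalized depth per type (OFF band = 0, ON band = 1):")
print(peaks, row.names = FALSE)

# band-model fitting from node annotations reproduces the known geometry
nodes <- function(which) {
  set.seed(99)
  xy <- data.frame(x = runif(60, 0, 210), y = runif(60, 0, 260))
  xy$z <- if (which == "off") geom$z0_um + geom$tilt_x * xy$x + geom$tilt_y * xy$y
  else geom$z0_um + geom$band_gap_um + geom$tilt_x * xy$x + geom$tilt_y * xy$y
  xy
}
bm <- fit_band_model(nodes("off"), nodes("on"))
refit <- normalize_depth(tab, bm)
message(sprintf("max |depth_norm difference| between true and fitted bands: %.2e",
                max(abs(refit$depth_norm - tab$depth_norm))))
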