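#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth:
# leading-edge closure movies (wild-type reference + three phenotype
# scenarios), amnioserosa apical-area traces, leading-edge protrusion
# frames, and an RNAi screen count table. Everything lands under
# results/data/ with its ground truth alongside.

suppressMessages(library(closuredyn))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- closure movies (frame interval 600 s, 0.5 um/px, 2% noise)")
rp <- render_params(um_per_px = 0.5, noise_sd = 0.02)
scenarios <- list(
  ref1 = list(v = 0.008, k_z = 0.004, H0 = 60, W0 = 240),
  ref2 = list(v = 0.008, k_z = 0.004, H0 = 60, W0 = 240),
  ref3 = list(v = 0.008, k_z = 0.004, H0 = 60, W0 = 240),
  wt_like = list(v = 0.008, k_z = 0.004, H0 = 60, W0 = 240),
  pbl_like = list(v = 0.008, k_z = 0.004, H0 = 70, W0 = 80),
  arf_like = list(v = 0.008, k_z = 0.001, H0 = 60, W0 = 240))
for (i in seq_along(scenarios)) {
  sc <- scenarios[[i]]
  nm <- names(scenarios)[i]
  traj <- simulate_closure_trajectory(
    closure_params(sc$v, sc$k_z, sc$H0, sc$W0, frame_interval = 600))
  mv <- render_closure_movie(traj, rp, seed = seed + i)
  write_movie_tiff(mv, file.path(out, paste0("movie_", nm, ".tif")))
  utils::write.csv(mv$truth, file.path(out, paste0("truth_", nm, ".csv")),
                   row.names = FALSE)
  message(sprintf("   %-8s %d frames (v=%g, k_z=%g)", nm,
                  nrow(traj$frames), sc$v, sc$k_z))
}

message("-- amnioserosa pulsation traces (wild type and pbl presets)")
for (g in c("wt", "pbl")) {
  sim <- simulate_amnioserosa_traces(preset_pulsation(g), seed = seed)
  write_traces_csv(sim, file.path(out, paste0("traces_", g, ".csv")))
  utils::write.csv(sim$truth, file.path(out, paste0("peaks_", g, ".csv")),
                   row.names = FALSE)
  message(sprintf("   %-3s %d cells, %d true cycles", g,
                  length(unique(sim$traces$cell_id)),
                  nrow(sim$truth) - length(unique(sim$truth$cell_id))))
}

message("-- leading-edge protrusion frames")
for (g in c("wt", "pbl")) {
  sim <- simulate_protrusion_frames(preset_protrusion(g), seed = seed)
  write_movie_tiff(sim$frames, file.path(out, paste0("protrusions_", g,
                                                     ".tif")))
  utils::write.csv(sim$truth,
                   file.path(out, paste0("protrusion_truth_", g, ".csv")),
                   row.names = FALSE)
  message(sprintf("   %-3s %d frames, %d truth objects", g,
                  length(sim$frames), nrow(sim$truth)))
}

message("-- RNAi screen count table")
tab <- simulate_screen_table(
  genes = c("shotgun_like", "pebble_like", "arf_like", "negative"),
  true_penetrance = c(0.93, 0.70, 0.43, 0.08),
  n_dsrna = 2, n_replicates = 3, n_scored = 21, seed = seed)
utils::write.csv(tab, file.path(out, "screen_table.csv"), row.names = FALSE)
message(sprintf("   %d records written", nrow(tab)))
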