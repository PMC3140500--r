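#!/usr/bin/env Rscript
# Segment every simulated closure movie and extract per-frame hole
# geometry (W, H, theta, area, shape metrics) into geometry CSVs.

suppressMessages(library(closuredyn))
data_dir <- "results/data"
out <- "results/geometry"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

movies <- list.files(data_dir, pattern = "^movie_.*\\.tif$")
for (m in movies) {
  nm <- sub("^movie_(.*)\\.tif$", "\\1", m)
  traj <- measure_stack(file.path(data_dir, m), um_per_px = 0.5,
                        frame_interval = 600)
  write_geometry_csv(traj, file.path(out, paste0("geometry_", nm, ".csv")))
  open <- traj$frames[!traj$frames$closed, ]
  message(sprintf("%-8s: %d frames measured, hole closes %s", nm,
                  nrow(traj$frames),
                  if (any(traj$frames$closed)) sprintf(
                    "by t = %d s", max(open$t_s) + 600) else "never"))
}
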