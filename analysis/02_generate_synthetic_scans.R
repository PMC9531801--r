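#!/usr/bin/env Rscript

# Stage 2: synthetic scanner images with ground truth.
#
# Renders stain scans (3 replicates each) for the free configuration and
# for a silk-like cloth (p = 0.04, f = 0.56) at the four bench positions.
# Images go to scratch/ (they are bulky and fully reproducible from the
# seeds recorded in the manifest); the ground-truth manifest travels with
# them. Stage 3 consumes this set through the ordinary imaging pipeline.

suppressPackageStartupMessages(library(bbcsim))

seed <- 20260102L
geometry <- experiment_geometry()
model <- emission_model(seed = seed)
# analysis-scale render: 1200 dpi keeps the full set small and quick while
# staining statistics stay well above the pixel pitch (~21 um)
settings <- render_settings(dpi = 1200, width_cm = 1, height_cm = 1,
                            seed = seed)

positions <- default_barrier_positions(geometry)
confs <- c(list(free = NULL),
           setNames(lapply(positions, barrier, p = 0.04, f = 0.56),
                    sprintf("pos%d", seq_along(positions))))

out_dir <- "scratch/synthetic_scans"
man <- generate_experiment_set(confs, model, geometry, settings,
                               replicates = 3, out_dir = out_dir)
csv <- read_manifest(file.path(out_dir, "manifest.csv"))
cat(sprintf("wrote %d scans to %s\n", nrow(csv), out_dir))
for (nm in names(confs))
  cat(sprintf("  %-5s area-based blocking %6.2f%%, volume-based %6.2f%%\n",
              nm, man$configurations[[nm]]$area_blocking_percent,
              man$configurations[[nm]]$volume_blocking_percent))
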