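#!/usr/bin/env Rscript
# Stage 1: build the virtual-species study inputs.
#
# Simulates the canonical synthetic climate landscape (four Gaussian-random-
# field layers, one carrying a south-to-north gradient), plants a
# two-variable Gaussian-niche species on it, and samples presence records
# in proportion to the true suitability. Writes the same CSV/ASCII-grid
# formats a real study would start from, so the rest of the workflow is
# agnostic about the data's synthetic origin.

suppressPackageStartupMessages(library(nichemax))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pre <- virtual_preset(seed = seed)
stack <- generate_landscape(pre$landscape)
truth <- true_suitability(stack, pre$species)
occ <- sample_presences(truth, pre$species$n_presences,
                        seed = pre$species$seed)

for (nm in names(stack$layers))
  write_ascii_grid(stack$layers[[nm]], file.path(out, paste0(nm, ".asc")))
write_ascii_grid(truth, file.path(out, "true_suitability.asc"))
write_occurrences(occ, file.path(out, "occurrences.csv"))
jsonlite::write_json(lapply(pre$scenario_deltas, as.list),
                     file.path(out, "scenario_deltas.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf(
  "simulated %d layers (%d x %d cells) and %d presences; truth > 0.5 on %.1f%% of cells",
  length(stack$layers), nrow(truth$values), ncol(truth$values), nrow(occ),
  100 * mean(truth$values > 0.5, na.rm = TRUE)))
message("inputs written under ", out)
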