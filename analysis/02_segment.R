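#!/usr/bin/env Rscript
# Stage 2 — trip segmentation. Run from the repository root after
# analysis/01_simulate.R.
#
# Splits each individual's fix stream into at-sea trips with the colony
# buffer rules (500 m inner buffer, 1 km return buffer, 14 min minimum
# return), drops incomplete trips, and summarises trip metrics.

suppressMessages(library(behavKBA))
source("analysis/common.R")

cfg <- workflow_config()
cfg$stages[c("classify", "ud", "overlap", "keyareas", "stats")] <- FALSE
run_pipeline(cfg)

tm <- read.csv(file.path(cfg$out_dir, "trip_metrics.csv"))
cat(sprintf("retained %d complete trips from %d individuals\n",
            nrow(tm), length(unique(tm$individual_id))))
cat(sprintf("trip distance %.1f +- %.1f km, max range %.1f +- %.1f km, ",
            mean(tm$total_distance_km), sd(tm$total_distance_km),
            mean(tm$max_distance_km), sd(tm$max_distance_km)))
cat(sprintf("duration %.1f +- %.1f h\n",
            mean(tm$duration_h), sd(tm$duration_h)))
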