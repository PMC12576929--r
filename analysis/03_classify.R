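#!/usr/bin/env Rscript
# Stage 3 — behavioural classification. Run from the repository root
# after analysis/02_segment.R.
#
# Fits the 3-state gamma/von Mises hidden Markov model per colony by
# maximum likelihood and decodes every trip with the Viterbi algorithm.
# The printed comparison of decoded state proportions against the
# generator's ground truth is the workflow's classification check.

suppressMessages(library(behavKBA))
source("analysis/common.R")

cfg <- workflow_config()
cfg$stages[c("ud", "overlap", "keyareas", "stats")] <- FALSE
run_pipeline(cfg)

dec <- read.csv(file.path(cfg$out_dir, "decoded.csv"))
sp <- state_proportions(dec)
cat("decoded per-colony behavioural proportions:\n")
print(sp$per_colony, digits = 3)
cat("colony-weighted grand means (%):\n")
print(round(100 * sp$grand, 1))

truth <- read.csv(file.path(cfg$out_dir, "truth.csv"))
tracks <- read.csv(file.path(cfg$out_dir, "tracks.csv"))
truth_key <- paste(tracks$individual_id, tracks$timestamp)
dec_truth <- truth$true_state[match(paste(dec$individual_id,
                                          dec$timestamp), truth_key)]
cat(sprintf("agreement with ground truth at decoded fixes: %.1f%%\n",
            100 * mean(dec$state == dec_truth, na.rm = TRUE)))

fits <- jsonlite::read_json(file.path(cfg$out_dir, "hmm_params.json"))
for (cid in names(fits)) {
  cat(sprintf("%s: fitted step means %s km\n", cid,
              paste(sprintf("%.3f", unlist(fits[[cid]]$step_mean)),
                    collapse = " / ")))
}
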