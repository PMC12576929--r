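#!/usr/bin/env Rscript
# Stage 6 — comparison models. Run from the repository root after
# analysis/05_keyareas.R.
#
# Fits the two headline models: a mixed-effects beta regression of the
# transformed capture proportions on behaviour subset (colony random
# intercept, subsample control as the reference level) and a linear
# mixed model of log10 key-area size (all-behaviour baseline), with
# Nakagawa marginal/conditional R^2.

suppressMessages(library(behavKBA))
source("analysis/common.R")

cfg <- workflow_config()
run_pipeline(cfg)

res <- jsonlite::read_json(file.path(cfg$out_dir, "stats.json"),
                           simplifyVector = TRUE)
if (!is.null(res$beta_glmm$subset_means)) {
  cat("beta mixed model, estimated capture by subset (response scale):\n")
  print(res$beta_glmm$subset_means, digits = 3)
  cat(sprintf("precision phi = %.2f, colony sd = %.3f\n",
              res$beta_glmm$phi, res$beta_glmm$sigma_group))
}
if (!is.null(res$lmm$coefficients)) {
  cat("\nlog10 key-area size model (contrasts vs all-behaviour):\n")
  print(res$lmm$coefficients, digits = 3)
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              res$lmm$r2_marginal, res$lmm$r2_conditional))
}
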