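# Shared workflow configuration: every numbered stage driver runs the
# same pipeline config against results/run/, so completed stages are
# reused via the content-hash cache and each script only pays for the
# stages it switches on.

workflow_config <- function(seed = 20120601) {
  out_dir <- file.path("results", "run")
  cfg <- default_run_config(out_dir = out_dir, seed = seed)
  cfg$generator <- default_config(
    n_colonies = 2, n_individuals_per_colony = 10,
    trips_per_individual = 3, trip_length = c(150, 300))
  cfg$params$rep_iterations <- 50
  cfg$params$min_individuals_site <- 8
  cfg$params$hmm_restarts <- 3
  cfg
}
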