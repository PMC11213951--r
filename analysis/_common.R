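# Shared plumbing for the numbered analysis scripts.
#
# Each script advances the pipeline by one stage. Completed stages are
# cached under scratch/ (keyed by configuration hash and stage) so the
# scripts can be run one after another without recomputation; deleting
# scratch/ forces a clean, fully deterministic rebuild from the config.

library(fparcdr)

analysis_config <- function() world_config(seed = 42L)

stage_artifacts <- function(stage, cfg = analysis_config()) {
  dir.create("scratch", showWarnings = FALSE)
  key <- substr(config_hash(cfg), 1, 8)
  cache <- file.path("scratch", sprintf("pipeline_%s_%s.rds", key, stage))
  if (file.exists(cache)) return(readRDS(cache))
  art <- suppressWarnings(run_pipeline(cfg, stages = stage, verbose = TRUE))
  saveRDS(art, cache)
  art
}

results_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
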