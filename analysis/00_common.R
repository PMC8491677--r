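# Shared setup for the numbered analysis scripts: one full pipeline run on
# the default synthetic study, cached so each script can be re-run alone.
library(conngrad)

seed <- 1
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)
cache <- sprintf("results/cache/run_seed%d.rds", seed)
if (file.exists(cache)) {
  run <- readRDS(cache)
} else {
  message("running the full pipeline (seed ", seed, ") ...")
  run <- suppressWarnings(run_pipeline(default_config(seed = seed)))
  saveRDS(run, cache)
}
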