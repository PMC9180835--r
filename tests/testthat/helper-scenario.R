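# Shared small scenario fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 11L) {
  scenarioConfig(seed = seed)
}

# Cached desk-scale reference bundle + ground truth.
small_scenario <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_config()
    bundle <- makeReference(cfg)
    .fixtures$small <- list(cfg = cfg, bundle = bundle,
                            truth = groundTruth(bundle, cfg))
  }
  .fixtures$small
}

# Cached desk-scale end-to-end pipeline run.
small_run <- function() {
  if (is.null(.fixtures$run)) {
    dir <- file.path(tempdir(), "memomir-small-run")
    .fixtures$run <- runPipeline(small_config(), dir)
  }
  .fixtures$run
}

# Cached full cs-memory-v1 run (used by the preset-recovery checks).
preset_run <- function() {
  if (is.null(.fixtures$presetrun)) {
    dir <- file.path(tempdir(), "memomir-preset-run")
    .fixtures$presetrun <- runPipeline(csMemoryScenario(), dir)
  }
  .fixtures$presetrun
}
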