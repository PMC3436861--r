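# The full-grid null simulation is shared by several tests; run it once
# per session and cache the records.
grid_cache <- new.env(parent = emptyenv())

acceptance_grid_records <- function() {
  if (is.null(grid_cache$records)) {
    cfg <- experiment_config(seed = 20260928L, replicates = 3L,
                             restarts = 20L)
    grid_cache$records <- run_grid_experiment(cfg)
  }
  grid_cache$records
}
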