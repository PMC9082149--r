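# Shared fixtures. The full end-to-end run is expensive, so it is computed
# once on first use and cached for the tests that inspect it.

.fixture_cache <- new.env(parent = emptyenv())

# One clean synthetic subject at the reference study layout (300 s, 125 Hz,
# 48/12/gap/228 split, 1-s segments), trained with a 200-epoch cap and
# early stopping.
e2e_run <- function() {
  if (is.null(.fixture_cache$e2e)) {
    s <- generate_record(synthetic_config(duration_s = 300, seed = 5))
    cfg <- default_run_config()
    cfg$seed <- 7L
    cfg$model$max_epochs <- 200L
    .fixture_cache$e2e <- list(
      subject = s,
      config = cfg,
      result = run_pipeline(s$record, cfg))
  }
  .fixture_cache$e2e
}

# A cheap pipeline configuration for determinism checks: whole pipeline,
# reduced durations and epochs.
cheap_config <- function(seed = 3L) {
  cfg <- default_run_config()
  cfg$seed <- seed
  cfg$split <- list(train_s = 16, val_s = 4, gap_s = 4, test_s = 24,
                    segment_s = 1L)
  cfg$model$max_epochs <- 25L
  cfg$model$early_stop_patience <- 0L
  cfg
}

cheap_record <- function(seed = 11L) {
  generate_record(synthetic_config(duration_s = 50, seed = seed),
                  record_id = "cheap")$record
}
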