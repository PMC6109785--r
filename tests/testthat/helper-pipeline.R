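# one small planted pipeline run shared across test files (built lazily)
.small_run_cache <- new.env(parent = emptyenv())

small_pipeline_run <- function() {
  if (is.null(.small_run_cache$run)) {
    cfg <- cohort_config(n_hc = 12, n_ms = 24, n_ms_short = 14,
                         grid_dims = c(16, 16, 10), n_networks = 4,
                         scenarios = c("1", "2", "3b", "4b"),
                         n_timepoints = 100)
    pc <- pipeline_config(cohort = cfg, n_perm = 150, ica_order = 6,
                          seed = 42)
    .small_run_cache$run <- run_pipeline(pc)
  }
  .small_run_cache$run
}
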