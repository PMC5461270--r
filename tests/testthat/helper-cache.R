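# Expensive default-configuration results shared across test files, computed
# once per test run. Everything is deterministic, so caching cannot change
# outcomes.

.sidestep_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.sidestep_cache[[name]])) {
    .sidestep_cache[[name]] <- force(expr)
  }
  .sidestep_cache[[name]]
}

default_sweep <- function() {
  cached("sweep", sweep_timings(sidestep_params(), t_start = 1.5,
                                spacing = 0.03, n = 101))
}

default_long_run <- function() {
  cached("long_run", run_sidestep(sidestep_params(), v_d = 2, duration = 60,
                                  log_diag = FALSE))
}

default_short_run <- function() {
  cached("short_run", run_sidestep(sidestep_params(), v_d = 2, duration = 2,
                                   log_diag = TRUE))
}
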