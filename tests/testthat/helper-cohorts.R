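# Scaled-down simulated cohorts shared by the decoding tests. Built once
# per test run and memoized; sizes are reduced relative to the emulated
# study (shorter probe gaps, fewer probes) so the whole suite stays fast,
# while effect gains stay at their study-condition values.

.cohort_cache <- new.env(parent = emptyenv())

# 4 participants x 2 sessions, planted effects at gain 0.5
planted_trials <- function() {
  if (is.null(.cohort_cache$planted)) {
    cfg <- synth_config(n_participants = 4, n_sessions = 2, n_probes = 14,
                        probe_gap = c(20, 30), task_duration = 450,
                        effects = default_effects(gain = 0.5), seed = 101)
    coh <- simulate_cohort(cfg, include_rest = FALSE)
    .cohort_cache$planted <- do.call(bind_trials, cohort_task_trials(coh))
  }
  .cohort_cache$planted
}

# 2 participants x 2 sessions, zero gain (global null)
null_trials <- function() {
  if (is.null(.cohort_cache$null)) {
    cfg <- synth_config(n_participants = 2, n_sessions = 2, n_probes = 12,
                        probe_gap = c(20, 30), task_duration = 400,
                        effects = default_effects(gain = 0), seed = 202)
    coh <- simulate_cohort(cfg, include_rest = FALSE)
    .cohort_cache$null <- do.call(bind_trials, cohort_task_trials(coh))
  }
  .cohort_cache$null
}

# reduced training schedule used with the scaled cohorts
fast_scnn <- function(max_epochs = 15) {
  scnn_config(learning_rate = 3e-3, max_epochs = max_epochs,
              patience = max_epochs)
}
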