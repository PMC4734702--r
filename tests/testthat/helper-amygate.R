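# shared miniature inputs: scaled-down Pavlovian schedule (3 channels,
# 4000 steps) and its parameter set; built in code, no stored fixtures
tiny_sched <- function(n_steps_per_epoch = 1000L, seed = 42L) {
  build_pavlovian_schedule(
    n_channels = 3, seed = seed, n_distractors = 0,
    epoch_steps = n_steps_per_epoch, cs_duration = 200L, r_duration = 150L,
    r_delay = 50L, ep1_reps = 1L, ep2_reps = 2L, test_cycles = 1L
  )
}

# quarter-length protocol with full-size pulse geometry: slow enough for
# learning and plan dynamics, fast enough for tests (40000 steps)
small_sched <- function(seed = 42L) {
  build_pavlovian_schedule(
    n_channels = 3, seed = seed, n_distractors = 0,
    epoch_steps = 10000L, ep1_reps = 2L, ep2_reps = 4L, test_cycles = 1L
  )
}

tiny_params <- function(...) rate_params(N = 3, ...)

activity_cols <- function(trace) {
  grep("^[xy]_", names(trace), value = TRUE)
}

weight_cols <- function(trace) {
  grep("^W_", names(trace), value = TRUE)
}
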