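# Shared fixtures, built in code. Schedules are cached per session so the
# many tests that need them do not regenerate them.

local({
  cache <- new.env(parent = emptyenv())
  fixture_schedules <<- function() {
    if (is.null(cache$s))
      cache$s <- list(hab = generate_task_schedule("habituation", 11),
                      cond = generate_task_schedule("conditioning", 12))
    cache$s
  }
})

# A trace set built directly from a dF/F0-scale signal matrix (f_rest 100),
# for deterministic imaging tests.
trace_set_from_signal <- function(signal_pct, cue, rate = 5,
                                  phase = "conditioning", f_rest = 100) {
  w <- trace_window(rate, 5, 15)
  neuron_trace_set("t1", "s1", phase, w, cue,
                   f_rest * (1 + signal_pct / 100))
}

# Spike train with prescribed ISIs (seconds), starting at `start`.
spike_train_from_isis <- function(isis, start = 1, pad = 1) {
  st <- start + c(0, cumsum(isis))
  spike_train_recording("isi", st, max(st) + pad)
}
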