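# Domain types, trial alignment and the on-disk round trips.

test_that("trace_window places cue onset at round(pre * rate)", {
  w <- trace_window(100, pre_s = 5, total_s = 15)
  expect_equal(w$n_samples, 1500L)
  expect_equal(w$t0_index, 500L)
  tt <- window_times(w)
  expect_equal(tt[w$t0_index + 1], 0)
  expect_equal(tt[1], -5)
})

test_that("schedule invariants are enforced", {
  tr <- data.frame(trial_index = 1:2, cue = c("CSplus", "CSminus"),
                   onset_s = c(30, 10), paired_us = FALSE)
  expect_error(trial_schedule(tr, "habituation"), "increasing")
  tr$onset_s <- c(30, 62)
  expect_error(trial_schedule(transform(tr, paired_us = c(TRUE, FALSE)),
                              "habituation"), "paired_us")
  tr$onset_s <- c(30, 1000)   # ITI far beyond bounds
  expect_error(trial_schedule(tr, "habituation"), "inter-trial")
  expect_error(
    trial_schedule(data.frame(trial_index = 1, cue = "CSboth",
                              onset_s = 30, paired_us = FALSE),
                   "habituation"),
    "unknown cue")
})

test_that("us_onsets anchors the airpuff 1.5 s after a paired cue onset", {
  s <- fixture_schedules()$cond
  on <- us_onsets(s)
  p <- s$trials$paired_us
  expect_equal(on[p], s$trials$onset_s[p] + 1.5)
  expect_true(all(is.na(on[!p])))
})

test_that("align_trials respects the coordinate convention", {
  w <- trace_window(100, pre_s = 5, total_s = 15)
  x <- rep(1.5, 5000)
  m <- align_trials(x, events = c(10, 20), window = w)
  expect_equal(dim(m), c(2L, 1500L))
  expect_true(all(m == 1.5))
  # unit impulse at the event lands on the t0 column
  x2 <- rep(0, 5000); x2[round(20 * 100) + 1] <- 1
  m2 <- align_trials(x2, events = 20, window = w)
  expect_equal(which(m2[1, ] == 1) - 1, w$t0_index)
})

test_that("align_trials is translation-equivariant and handles edges", {
  w <- trace_window(10, pre_s = 2, total_s = 5)
  set.seed(1)
  x <- rnorm(400)
  ev <- c(10, 20, 30)
  m1 <- align_trials(x, ev, w)
  m2 <- align_trials(c(rep(NA, 70), x), ev + 7, w)  # shift series and events by 7 s
  expect_equal(unclass(m1)[, ], unclass(m2)[, ], ignore_attr = TRUE)
  # event too close to the edge: drop with warning, or fail in strict mode
  expect_warning(m3 <- align_trials(x, c(1, 20), w), "too close")
  expect_equal(nrow(m3), 1L)
  expect_equal(attr(m3, "dropped_events"), 1)
  expect_error(align_trials(x, c(1, 20), w, on_edge = "error"), "too close")
})

test_that("every record type round-trips through write_session/load_session", {
  dir <- withr::local_tempdir()
  s <- fixture_schedules()$hab
  write_session(s, file.path(dir, "sched.csv"))
  s2 <- load_session(file.path(dir, "sched.csv"), "schedule")
  expect_equal(s2$trials$cue, s$trials$cue)
  expect_equal(s2$trials$onset_s, s$trials$onset_s, tolerance = 1e-8)
  expect_equal(s2$phase, s$phase)
  expect_equal(nrow(s2$trials), 65L)

  rec <- spike_train_recording("n1", c(0.5, 1.25, 3.75), 10, c(5, 7))
  write_session(rec, file.path(dir, "n1.txt"))
  rec2 <- load_session(file.path(dir, "n1.txt"), "spikes")
  expect_equal(rec2$spike_times_s, rec$spike_times_s, tolerance = 1e-8)
  expect_equal(rec2$fs_event_times_s, rec$fs_event_times_s)
  expect_equal(rec2$neuron_id, "n1")

  w <- trace_window(5, 5, 15)
  ts <- neuron_trace_set("c1", "hab1", "habituation", w,
                         c("CSplus", "CSminus"),
                         matrix(rnorm(2 * w$n_samples, 100, 5), 2))
  write_session(ts, file.path(dir, "c1.csv"))
  ts2 <- load_session(file.path(dir, "c1.csv"), "traces")
  expect_equal(ts2$raw_f, ts$raw_f, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(ts2$cue_per_trial, ts$cue_per_trial)

  bw <- trace_window(10, 5, 15)
  bs <- behavior_session("m1", "conditioning", c("CSplus", "CSminus"),
                         matrix(2000 + rnorm(2 * bw$n_samples), 2), bw)
  write_session(bs, file.path(dir, "m1.csv"))
  bs2 <- load_session(file.path(dir, "m1.csv"), "behavior")
  expect_equal(bs2$eye_area, bs$eye_area, tolerance = 1e-7, ignore_attr = TRUE)

  ps <- photometry_series("a1", "ACh", rpois(2000, 50),
                          data.frame(onset_s = c(6, 12), cue = "CSplus",
                                     phase = "habituation"))
  write_session(ps, file.path(dir, "a1.csv"))
  ps2 <- load_session(file.path(dir, "a1.csv"), "photometry")
  expect_equal(ps2$counts, ps$counts)
  expect_equal(ps2$events$onset_s, ps$events$onset_s)
})

test_that("empty trial list writes a valid file with zero data rows", {
  dir <- withr::local_tempdir()
  s <- trial_schedule(data.frame(trial_index = integer(), cue = character(),
                                 onset_s = numeric(), paired_us = logical()),
                      "habituation")
  write_session(s, file.path(dir, "empty.csv"))
  s2 <- load_session(file.path(dir, "empty.csv"), "schedule")
  expect_equal(nrow(s2$trials), 0L)
})

test_that("malformed spike files are rejected with a named invariant", {
  dir <- withr::local_tempdir()
  rec <- spike_train_recording("n1", c(0.05, 0.1), 1)
  write_session(rec, file.path(dir, "bad.txt"))
  writeLines(c("0.1", "0.05"), file.path(dir, "bad.txt"))
  expect_error(load_session(file.path(dir, "bad.txt"), "spikes"), "not sorted")
})

test_that("analysis configuration round-trips through YAML", {
  dir <- withr::local_tempdir()
  cfg <- analysis_config(alpha = 0.01, rng_seed = 99L)
  write_config(cfg, file.path(dir, "cfg.yaml"))
  cfg2 <- read_config(file.path(dir, "cfg.yaml"))
  expect_equal(cfg2$alpha, 0.01)
  expect_equal(cfg2$rng_seed, 99L)
  expect_equal(cfg2$cr_window, c(0, 1.5))
  expect_error(analysis_config(alpha = 1.2), "alpha")
})
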