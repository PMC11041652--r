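#' Analysis configuration
#'
#' Bundles the significance level and the time windows shared across the
#' imaging, behavior and photometry stages. All windows are in seconds on
#' the trial axis (time 0 at cue onset, windows half-open `[start, end)`).
#'
#' @param alpha significance level for all response classifications
#'   (default 0.05).
#' @param cr_window conditioned-response window, seconds from cue onset to
#'   airpuff onset (default `c(0, 1.5)`).
#' @param imaging_baseline_window_s length of the pre-cue baseline AUC
#'   window for imaging classification, seconds (default 1.5).
#' @param dff_f0_window_s length of the pre-event F0 window for dF/F0,
#'   seconds (default 3).
#' @param behavior_f0_window_s length of the pre-cue eye-area normalization
#'   window, seconds (default 5).
#' @param rng_seed integer seed used by seeded analysis steps (embedding,
#'   decoding splits).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05,
                            cr_window = c(0, 1.5),
                            imaging_baseline_window_s = 1.5,
                            dff_f0_window_s = 3,
                            behavior_f0_window_s = 5,
                            rng_seed = 1L) {
  assert_that(is_scalar_number(alpha) && alpha > 0 && alpha < 1,
              "alpha must be in (0, 1)")
  assert_that(length(cr_window) == 2 && cr_window[2] > cr_window[1],
              "cr_window must be c(start, end) with end > start")
  assert_that(imaging_baseline_window_s > 0, "imaging baseline window must be positive")
  assert_that(dff_f0_window_s > 0, "dF/F0 window must be positive")
  assert_that(behavior_f0_window_s > 0, "behavior F0 window must be positive")
  structure(list(alpha = alpha,
                 cr_window = as.numeric(cr_window),
                 imaging_baseline_window_s = imaging_baseline_window_s,
                 dff_f0_window_s = dff_f0_window_s,
                 behavior_f0_window_s = behavior_f0_window_s,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Trial time window
#'
#' Describes the trial-aligned time axis: sampling rate, seconds of
#' pre-event baseline included, and total trial length. Sample `t0_index`
#' (zero-based, `round(pre_s * rate)`) falls at event onset, i.e. trial
#' time 0.
#'
#' @param sample_rate_hz sampling rate in Hz.
#' @param pre_s seconds of pre-event history included (default 5).
#' @param total_s total trial length in seconds (default 15).
#' @return An object of class `trace_window`.
#' @export
trace_window <- function(sample_rate_hz, pre_s = 5, total_s = 15) {
  assert_that(sample_rate_hz > 0, "sample rate must be positive")
  assert_that(pre_s >= 0 && pre_s < total_s, "pre_s must satisfy 0 <= pre_s < total_s")
  structure(list(sample_rate_hz = sample_rate_hz,
                 pre_s = pre_s,
                 total_s = total_s,
                 n_samples = as.integer(round(total_s * sample_rate_hz)),
                 t0_index = as.integer(round(pre_s * sample_rate_hz))),
            class = "trace_window")
}

#' Trial time axis for a window
#'
#' @param window a [trace_window()].
#' @return Numeric vector of sample times (seconds, 0 = event onset); sample
#'   `t0_index + 1` is time 0.
#' @export
window_times <- function(window) {
  stopifnot(inherits(window, "trace_window"))
  (seq_len(window$n_samples) - 1 - window$t0_index) / window$sample_rate_hz
}

cue_levels <- c("CSplus", "CSminus", "US_unpredicted")
phase_levels <- c("habituation", "conditioning")

check_cues <- function(cue) {
  bad <- setdiff(unique(as.character(cue)), cue_levels)
  assert_that(length(bad) == 0, "unknown cue label(s): %s", paste(bad, collapse = ", "))
  as.character(cue)
}

check_phase <- function(phase) {
  assert_that(length(phase) == 1 && phase %in% phase_levels,
              "phase must be one of: %s", paste(phase_levels, collapse = ", "))
  phase
}

#' Trial schedule
#'
#' Ordered list of trials for one session: cue identity, onset time and
#' whether the cue is paired with the airpuff. Task constants follow the
#' conditioning protocol: 1-s cues, a 0.5-s delay between cue offset and
#' airpuff, a 0.5-s airpuff, and inter-trial intervals drawn from 30-45 s.
#'
#' @param trials data frame with columns `trial_index`, `cue`, `onset_s`,
#'   `paired_us`.
#' @param phase `"habituation"` or `"conditioning"`.
#' @param cs_duration_s cue duration, seconds (1).
#' @param us_delay_s delay from cue offset to airpuff onset, seconds (0.5).
#' @param us_duration_s airpuff duration, seconds (0.5).
#' @param iti_bounds_s inter-trial-interval bounds, seconds (`c(30, 45)`).
#' @return An object of class `trial_schedule`.
#' @export
trial_schedule <- function(trials, phase,
                           cs_duration_s = 1, us_delay_s = 0.5,
                           us_duration_s = 0.5, iti_bounds_s = c(30, 45)) {
  phase <- check_phase(phase)
  need <- c("trial_index", "cue", "onset_s", "paired_us")
  assert_that(all(need %in% names(trials)),
              "schedule needs columns: %s", paste(need, collapse = ", "))
  trials <- trials[need]
  trials$cue <- check_cues(trials$cue)
  trials$paired_us <- as.logical(trials$paired_us)
  assert_that(!anyNA(trials$onset_s) && all(diff(trials$onset_s) > 0),
              "trial onsets must be strictly increasing")
  if (any(trials$paired_us))
    assert_that(all(trials$cue[trials$paired_us] == "CSplus") &&
                  phase == "conditioning",
                "paired_us may be TRUE only for CSplus trials in conditioning")
  x <- structure(list(trials = trials, phase = phase,
                      cs_duration_s = cs_duration_s, us_delay_s = us_delay_s,
                      us_duration_s = us_duration_s,
                      iti_bounds_s = as.numeric(iti_bounds_s)),
                 class = "trial_schedule")
  validate_iti(x)
  x
}

# Trial footprint (seconds occupied from onset to end of the last stimulus).
trial_length_s <- function(schedule, cue) {
  ifelse(cue == "US_unpredicted",
         schedule$us_duration_s,
         schedule$cs_duration_s + schedule$us_delay_s + schedule$us_duration_s)
}

validate_iti <- function(schedule) {
  tr <- schedule$trials
  if (nrow(tr) < 2) return(invisible(TRUE))
  gaps <- diff(tr$onset_s)
  lens <- trial_length_s(schedule, tr$cue)[-nrow(tr)]
  iti <- gaps - lens
  b <- schedule$iti_bounds_s
  assert_that(all(iti >= b[1] - 1e-6 & iti <= b[2] + 1e-6),
              "inter-trial intervals outside [%g, %g] s", b[1], b[2])
  invisible(TRUE)
}

#' US onset time for a trial (seconds from session start), or NA
#'
#' @param schedule a [trial_schedule()].
#' @return Numeric vector, one per trial: onset of the airpuff for paired
#'   CS+ trials and for unpredicted-US trials, `NA` otherwise.
#' @export
us_onsets <- function(schedule) {
  tr <- schedule$trials
  out <- rep(NA_real_, nrow(tr))
  out[tr$cue == "US_unpredicted"] <- tr$onset_s[tr$cue == "US_unpredicted"]
  p <- tr$paired_us %in% TRUE
  out[p] <- tr$onset_s[p] + schedule$cs_duration_s + schedule$us_delay_s
  out
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule (%s): %d trials\n", x$phase, nrow(x$trials)))
  print(table(x$trials$cue))
  invisible(x)
}

#' Spike-train recording
#'
#' Spike times for one neuron together with the foot-shock stimulation
#' onsets delivered during the recording.
#'
#' @param neuron_id identifier string.
#' @param spike_times_s sorted nonnegative spike times, seconds.
#' @param duration_s recording duration, seconds.
#' @param fs_event_times_s foot-shock onset times, seconds (may be empty).
#' @param fs_duration_s foot-shock duration, seconds (0.5).
#' @return An object of class `spike_train`.
#' @export
spike_train_recording <- function(neuron_id, spike_times_s, duration_s,
                                  fs_event_times_s = numeric(),
                                  fs_duration_s = 0.5) {
  spike_times_s <- as.numeric(spike_times_s)
  assert_that(!is.unsorted(spike_times_s, strictly = FALSE),
              "spike times not sorted")
  assert_that(all(spike_times_s >= 0), "negative spike times")
  assert_that(length(spike_times_s) == 0 ||
                spike_times_s[length(spike_times_s)] <= duration_s + 1e-9,
              "spike times exceed recording duration")
  assert_that(!is.unsorted(fs_event_times_s), "foot-shock onsets not sorted")
  structure(list(neuron_id = as.character(neuron_id),
                 spike_times_s = spike_times_s,
                 duration_s = duration_s,
                 fs_event_times_s = as.numeric(fs_event_times_s),
                 fs_duration_s = fs_duration_s,
                 n_fs_trials = length(fs_event_times_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train %s: %d spikes over %.1f s, %d foot-shock trials\n",
              x$neuron_id, length(x$spike_times_s), x$duration_s, x$n_fs_trials))
  invisible(x)
}

#' Trial-aligned fluorescence traces for one neuron
#'
#' @param neuron_id,session_id identifier strings; `neuron_id` is the
#'   longitudinal tracking ID shared across sessions.
#' @param phase `"habituation"` or `"conditioning"`.
#' @param window a [trace_window()] describing the trial axis.
#' @param cue_per_trial cue label per trial (row of `raw_f`).
#' @param raw_f trials x samples matrix of raw fluorescence.
#' @param dff_pct optional trials x samples matrix of percent dF/F0, as
#'   produced by [compute_dff()].
#' @return An object of class `trace_set`.
#' @export
neuron_trace_set <- function(neuron_id, session_id, phase, window,
                             cue_per_trial, raw_f, dff_pct = NULL) {
  stopifnot(inherits(window, "trace_window"))
  phase <- check_phase(phase)
  raw_f <- as.matrix(raw_f)
  cue_per_trial <- check_cues(cue_per_trial)
  assert_that(nrow(raw_f) == length(cue_per_trial),
              "cue_per_trial length (%d) != trial count (%d)",
              length(cue_per_trial), nrow(raw_f))
  assert_that(ncol(raw_f) == window$n_samples,
              "raw_f has %d samples per trial, window expects %d",
              ncol(raw_f), window$n_samples)
  if (!is.null(dff_pct)) {
    dff_pct <- as.matrix(dff_pct)
    assert_that(all(dim(dff_pct) == dim(raw_f)), "dff_pct dimensions differ from raw_f")
  }
  structure(list(neuron_id = as.character(neuron_id),
                 session_id = as.character(session_id),
                 phase = phase, window = window,
                 cue_per_trial = cue_per_trial,
                 raw_f = raw_f, dff_pct = dff_pct),
            class = "trace_set")
}

#' Fiber-photometry photon-count series
#'
#' @param animal_id identifier string.
#' @param sensor sensor label, one of `"Glu"`, `"GABA"`, `"FiveHT"`,
#'   `"ACh"`, `"other"`.
#' @param counts nonnegative integer photon counts per time bin.
#' @param events data frame with columns `onset_s`, `cue`, `phase`.
#' @param bin_width_s bin width in seconds (0.01, i.e. 100 Hz).
#' @return An object of class `photometry_series`.
#' @export
photometry_series <- function(animal_id, sensor, counts, events,
                              bin_width_s = 0.01) {
  sensors <- c("Glu", "GABA", "FiveHT", "ACh", "other")
  assert_that(sensor %in% sensors, "sensor must be one of: %s",
              paste(sensors, collapse = ", "))
  assert_that(bin_width_s > 0, "bin width must be positive")
  counts <- as.numeric(counts)
  assert_that(all(counts >= 0), "photon counts must be nonnegative")
  need <- c("onset_s", "cue", "phase")
  assert_that(all(need %in% names(events)),
              "events need columns: %s", paste(need, collapse = ", "))
  events$cue <- check_cues(events$cue)
  assert_that(all(events$phase %in% phase_levels), "unknown phase label in events")
  dur <- length(counts) * bin_width_s
  assert_that(all(events$onset_s >= 0 & events$onset_s <= dur),
              "event onsets outside series duration")
  structure(list(animal_id = as.character(animal_id), sensor = sensor,
                 bin_width_s = bin_width_s, counts = counts,
                 events = events[need]),
            class = "photometry_series")
}

#' Eyeblink behavior session
#'
#' Per-trial eye-area traces (pixels, 10 Hz) with cue labels.
#'
#' @param mouse_id identifier string.
#' @param phase `"habituation"` or `"conditioning"`.
#' @param cue_per_trial cue label per trial.
#' @param eye_area trials x samples matrix of eye-area pixel counts.
#' @param window a [trace_window()]; must have a 10 Hz rate.
#' @param norm_eye_pct optional normalized matrix from
#'   [normalize_eye_trace()].
#' @return An object of class `behavior_session`.
#' @export
behavior_session <- function(mouse_id, phase, cue_per_trial, eye_area,
                             window = trace_window(10, 5, 15),
                             norm_eye_pct = NULL) {
  stopifnot(inherits(window, "trace_window"))
  assert_that(window$sample_rate_hz == 10, "behavior sessions are sampled at 10 Hz")
  phase <- check_phase(phase)
  eye_area <- as.matrix(eye_area)
  cue_per_trial <- check_cues(cue_per_trial)
  assert_that(nrow(eye_area) == length(cue_per_trial),
              "cue_per_trial length != trial count")
  assert_that(ncol(eye_area) == window$n_samples,
              "eye_area has %d samples per trial, window expects %d",
              ncol(eye_area), window$n_samples)
  if (!is.null(norm_eye_pct)) {
    norm_eye_pct <- as.matrix(norm_eye_pct)
    assert_that(all(dim(norm_eye_pct) == dim(eye_area)),
                "norm_eye_pct dimensions differ from eye_area")
  }
  structure(list(mouse_id = as.character(mouse_id), phase = phase,
                 window = window, cue_per_trial = cue_per_trial,
                 eye_area = eye_area, norm_eye_pct = norm_eye_pct),
            class = "behavior_session")
}
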