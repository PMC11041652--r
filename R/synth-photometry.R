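#' Parameters for a synthetic photometry sensor
#'
#' Describes a photon-count (100 Hz) neurotransmitter-sensor recording over
#' one habituation and one conditioning session. Counts are Poisson around
#' a baseline rate modulated by unit-peak transients at each cue and
#' airpuff. A `"stable"` sensor (glutamate / GABA / serotonin-like) keeps
#' identical transient amplitudes across cues and phases; a
#' `"potentiating"` sensor (acetylcholine-like) doubles its CS+ amplitude
#' during conditioning.
#'
#' @param sensor_profile `"stable"` or `"potentiating"`.
#' @param sensor sensor label stored on the series (default `"Glu"` for
#'   stable, `"ACh"` for potentiating).
#' @param base_rate mean photons per 10-ms bin (default 50).
#' @param amp_hab,amp_cond named numeric vectors `c(csplus=, csminus=, us=)`
#'   of multiplicative transient amplitudes per phase. Defaults: 0.4 for
#'   both cues and 1.0 for the airpuff; for a potentiating sensor the
#'   conditioning CS+ amplitude is 0.8.
#' @param rise_s,decay_s transient kernel time constants, seconds
#'   (defaults 0.05, 0.5).
#' @param bin_width_s bin width, seconds (0.01).
#' @param seed master seed.
#' @return An object of class `photometry_params`.
#' @export
photometry_params <- function(sensor_profile = c("stable", "potentiating"),
                              sensor = NULL, base_rate = 50,
                              amp_hab = NULL, amp_cond = NULL,
                              rise_s = 0.05, decay_s = 0.5,
                              bin_width_s = 0.01, seed = 1L) {
  sensor_profile <- match.arg(sensor_profile)
  sensor <- sensor %||% if (sensor_profile == "stable") "Glu" else "ACh"
  default_amp <- c(csplus = 0.4, csminus = 0.4, us = 1.0)
  amp_hab <- amp_hab %||% default_amp
  amp_cond <- amp_cond %||% {
    a <- default_amp
    if (sensor_profile == "potentiating") a["csplus"] <- 0.8
    a
  }
  for (a in list(amp_hab, amp_cond))
    assert_that(all(c("csplus", "csminus", "us") %in% names(a)) && all(a >= 0),
                "amplitudes must be named nonnegative c(csplus=, csminus=, us=)")
  assert_that(base_rate > 0, "base_rate must be positive")
  structure(as.list(environment())[c(
    "sensor_profile", "sensor", "base_rate", "amp_hab", "amp_cond",
    "rise_s", "decay_s", "bin_width_s", "seed")],
    class = "photometry_params")
}

#' Generate a synthetic photometry series
#'
#' Simulates the two sessions back to back (conditioning appended 60 s
#' after the end of habituation); each event in the returned series carries
#' its phase label. Counts per bin are
#' `Poisson(base_rate * (1 + sum of amplitude-scaled transients))`.
#'
#' @param params a [photometry_params()].
#' @param schedule_hab,schedule_cond [trial_schedule()]s for the two phases.
#' @return A list with `series` (a [photometry_series()]) and `params`.
#' @export
generate_photometry <- function(params, schedule_hab, schedule_cond) {
  stopifnot(inherits(params, "photometry_params"))
  p <- params
  scheds <- list(habituation = schedule_hab, conditioning = schedule_cond)
  amps <- list(habituation = p$amp_hab, conditioning = p$amp_cond)
  kern_len <- ceiling((5 * p$decay_s + 0.2) / p$bin_width_s)
  kern <- transient_kernel((seq_len(kern_len) - 1) * p$bin_width_s,
                           p$rise_s, p$decay_s)
  all_counts <- list()
  all_events <- list()
  offset <- 0
  counts_phase <- with_seed(p$seed, {
    for (ph in names(scheds)) {
      sch <- scheds[[ph]]
      tr <- sch$trials
      dur <- max(tr$onset_s) + 20
      n_bins <- ceiling(dur / p$bin_width_s)
      rate_mult <- rep(1, n_bins)
      add_transient <- function(onset, amp) {
        i0 <- floor(onset / p$bin_width_s) + 1
        idx <- i0:min(n_bins, i0 + kern_len - 1)
        rate_mult[idx] <<- rate_mult[idx] + amp * kern[seq_along(idx)]
      }
      a <- amps[[ph]]
      for (t_i in seq_len(nrow(tr))) {
        cue <- tr$cue[t_i]
        if (cue == "CSplus") add_transient(tr$onset_s[t_i], a[["csplus"]])
        else if (cue == "CSminus") add_transient(tr$onset_s[t_i], a[["csminus"]])
        else add_transient(tr$onset_s[t_i], a[["us"]])
        if (tr$paired_us[t_i])
          add_transient(tr$onset_s[t_i] + sch$cs_duration_s + sch$us_delay_s,
                        a[["us"]])
      }
      all_counts[[ph]] <- stats::rpois(n_bins, p$base_rate * rate_mult)
      all_events[[ph]] <- data.frame(onset_s = tr$onset_s + offset,
                                     cue = tr$cue, phase = ph)
      offset <- offset + n_bins * p$bin_width_s + 60
      all_counts[[paste0(ph, "_gap")]] <-
        stats::rpois(round(60 / p$bin_width_s), p$base_rate)
    }
    all_counts
  })
  series <- photometry_series(
    animal_id = paste0(p$sensor, "_1"), sensor = p$sensor,
    counts = unlist(counts_phase, use.names = FALSE),
    events = do.call(rbind, all_events), bin_width_s = p$bin_width_s)
  list(series = series, params = p)
}
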