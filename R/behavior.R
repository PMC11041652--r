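# Eyeblink conditioned-response quantification.

#' Normalize eye-area traces to the pre-cue baseline
#'
#' Rescales each trial to percent of its own pre-cue baseline: the mean
#' eye area over the `behavior_f0_window_s` seconds (default 5) before cue
#' onset maps to 100. Trials with a non-positive baseline (tracking
#' dropouts) are dropped with a warning.
#'
#' @param session a [behavior_session()].
#' @param cfg an [analysis_config()].
#' @return The session with `norm_eye_pct` filled in (dropped trials
#'   removed; their indices in attribute `dropped_trials`).
#' @export
normalize_eye_trace <- function(session, cfg = analysis_config()) {
  stopifnot(inherits(session, "behavior_session"))
  tt <- window_times(session$window)
  basef <- tt >= -cfg$behavior_f0_window_s & tt < 0
  assert_that(any(basef), "baseline window has no samples")
  b <- rowMeans(session$eye_area[, basef, drop = FALSE])
  bad <- !(b > 0)
  if (any(bad))
    warning(sprintf("dropping %d trial(s) with non-positive baseline: %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
  keep <- which(!bad)
  out <- behavior_session(session$mouse_id, session$phase,
                          session$cue_per_trial[keep],
                          session$eye_area[keep, , drop = FALSE],
                          session$window,
                          norm_eye_pct = 100 * session$eye_area[keep, , drop = FALSE] / b[keep])
  attr(out, "dropped_trials") <- which(bad)
  out
}

#' Conditioned-response amplitude of one normalized trial
#'
#' Mean normalized eye area over the conditioned-response window (cue
#' onset to airpuff onset, default 0-1.5 s, half-open). Lower values mean
#' a stronger anticipatory blink.
#'
#' @param trial_norm normalized trace of one trial (percent).
#' @param window the session's [trace_window()].
#' @param cfg an [analysis_config()] (supplies `cr_window`).
#' @return CR amplitude in percent.
#' @export
cr_amplitude <- function(trial_norm, window, cfg = analysis_config()) {
  tt <- window_times(window)
  inw <- tt >= cfg$cr_window[1] & tt < cfg$cr_window[2]
  assert_that(any(inw), "conditioned-response window contains no samples")
  mean(trial_norm[inw])
}

#' Summarize a behavior session
#'
#' Normalizes (if needed), computes per-trial CR amplitudes over the CR
#' window, and the session discrimination score. Unpredicted-US trials do
#' not enter the cue means.
#'
#' @param session a [behavior_session()].
#' @param cfg an [analysis_config()].
#' @return An object of class `behavior_summary` with
#'   `cr_amplitude_per_trial`, `cr_mean_csplus`, `cr_mean_csminus`,
#'   `discrimination_score` and `phase`.
#' @export
behavior_summary <- function(session, cfg = analysis_config()) {
  stopifnot(inherits(session, "behavior_session"))
  if (is.null(session$norm_eye_pct))
    session <- normalize_eye_trace(session, cfg)
  cr <- apply(session$norm_eye_pct, 1, cr_amplitude,
              window = session$window, cfg = cfg)
  cues <- session$cue_per_trial
  assert_that(any(cues == "CSplus") && any(cues == "CSminus"),
              "session lacks trials of both cue types")
  mp <- mean(cr[cues == "CSplus"])
  mm <- mean(cr[cues == "CSminus"])
  structure(list(cr_amplitude_per_trial = cr,
                 cue_per_trial = cues,
                 cr_mean_csplus = mp, cr_mean_csminus = mm,
                 discrimination_score = mm - mp,
                 phase = session$phase,
                 mouse_id = session$mouse_id),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behavior %s (%s): CS+ %.1f%%, CS- %.1f%%, discrimination %.1f\n",
              x$mouse_id, x$phase, x$cr_mean_csplus, x$cr_mean_csminus,
              x$discrimination_score))
  invisible(x)
}

#' Cue discrimination score
#'
#' Mean CS- conditioned-response amplitude minus mean CS+ amplitude
#' (percent points). Positive when the anticipatory blink is selective for
#' the punishment-predictive cue.
#'
#' @param x a [behavior_summary()] or a [behavior_session()].
#' @param cfg an [analysis_config()] (used when `x` is a session).
#' @return The discrimination score.
#' @export
discrimination_score <- function(x, cfg = analysis_config()) {
  if (inherits(x, "behavior_session")) x <- behavior_summary(x, cfg)
  stopifnot(inherits(x, "behavior_summary"))
  x$discrimination_score
}

#' Paired learning test on discrimination scores
#'
#' Paired t-test of per-mouse discrimination scores, habituation versus
#' conditioning (one-sided alternatives are the caller's choice via
#' `alternative`).
#'
#' @param hab_scores,cond_scores per-mouse discrimination scores, matched
#'   order.
#' @param alternative passed to [stats::t.test()] (default two-sided, with
#'   conditioning as the first group).
#' @return The `htest` object.
#' @export
discrimination_learning_test <- function(hab_scores, cond_scores,
                                         alternative = "two.sided") {
  assert_that(length(hab_scores) == length(cond_scores),
              "score vectors differ in length")
  assert_that(length(hab_scores) >= 2, "need at least 2 mice")
  stats::t.test(cond_scores, hab_scores, paired = TRUE,
                alternative = alternative)
}
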