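#' Generate a Pavlovian conditioning task schedule
#'
#' Builds one session of the cue-punishment task. A habituation session has
#' 30 CS+ trials, 30 CS- trials and 5 unpredicted airpuffs (US) in random
#' order with no pairing; a conditioning session has 30 CS+ trials, each
#' paired with a delayed airpuff, and 30 CS- trials. Inter-trial intervals
#' (end of one trial to onset of the next) are i.i.d. uniform on 30-45 s.
#'
#' @param phase `"habituation"` or `"conditioning"`.
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @param first_onset_s onset of the first trial, seconds from session
#'   start (default 30, leaving ample pre-trial history for alignment).
#' @return A [trial_schedule()].
#' @examples
#' s <- generate_task_schedule("habituation", seed = 1)
#' table(s$trials$cue)
#' @export
generate_task_schedule <- function(phase, seed, first_onset_s = 30) {
  phase <- check_phase(phase)
  with_seed(seed, {
    if (phase == "habituation") {
      cues <- sample(c(rep("CSplus", 30), rep("CSminus", 30),
                       rep("US_unpredicted", 5)))
      paired <- rep(FALSE, length(cues))
    } else {
      cues <- sample(c(rep("CSplus", 30), rep("CSminus", 30)))
      paired <- cues == "CSplus"
    }
    n <- length(cues)
    sched0 <- list(cs_duration_s = 1, us_delay_s = 0.5, us_duration_s = 0.5)
    lens <- ifelse(cues == "US_unpredicted", sched0$us_duration_s,
                   sched0$cs_duration_s + sched0$us_delay_s + sched0$us_duration_s)
    itis <- stats::runif(n - 1, 30, 45)
    onsets <- first_onset_s + c(0, cumsum(lens[-n] + itis))
    trial_schedule(data.frame(trial_index = seq_len(n), cue = cues,
                              onset_s = onsets, paired_us = paired),
                   phase = phase)
  })
}
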