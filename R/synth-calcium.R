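# Unit-peak double-exponential transient evaluated on a sample grid
# (zero before onset). Normalized by its maximum over the grid so planted
# peak amplitudes are exact at the recorded sampling rate.
transient_kernel <- function(t, rise_s, decay_s) {
  k <- ifelse(t < 0, 0, (1 - exp(-t / rise_s)) * exp(-t / decay_s))
  mx <- max(k)
  if (mx > 0) k / mx else k
}

#' Parameters for a synthetic calcium-imaging cohort
#'
#' Describes a longitudinally tracked population of neurons imaged during
#' habituation and conditioning. Each neuron is excited, inhibited or
#' non-responsive; responsive neurons carry a cue-locked dF/F0 transient on
#' CS+ trials whose amplitude grows from habituation to conditioning
#' (planted plasticity), and respond to the airpuff in the same direction.
#' During habituation only a fraction `hab_response_prob` of the responsive
#' neurons already express their (smaller) response; the rest become new
#' responders during conditioning, which is what shifts the class
#' distribution across learning. A per-trial latent scales all responsive
#' neurons together, providing the trial-to-trial covariation that the
#' behavior generator and the decoder tests rely on.
#'
#' @param n_neurons cohort size (default 50).
#' @param class_probs probabilities of excited / inhibited / nonresponsive
#'   (defaults 0.36 / 0.14 / 0.50).
#' @param amp_hab,amp_cond mean cue-locked dF/F0 peak amplitude (percent)
#'   per phase for responsive neurons (defaults 10 and 20; conditioning
#'   larger plants plasticity).
#' @param hab_response_prob probability a responsive neuron already
#'   responds during habituation (default 0.5).
#' @param rise_s,decay_s transient kernel time constants, seconds
#'   (defaults 0.05 and 0.5, GCaMP6f-like).
#' @param noise_sd dF/F0 noise standard deviation, percent (default 5).
#' @param sample_rate_hz imaging rate, Hz (default 5).
#' @param f_rest resting fluorescence, arbitrary units (default 100).
#' @param amp_latent_sd relative SD of the shared per-trial amplitude
#'   latent (default 0.3).
#' @param amp_jitter relative SD of per-neuron-per-trial amplitude jitter
#'   (default 0.1).
#' @param us_amp_scale US transient amplitude relative to the cue amplitude
#'   (default 1).
#' @param seed master seed.
#' @return An object of class `calcium_cohort_params`.
#' @export
calcium_cohort_params <- function(n_neurons = 50,
                                  class_probs = c(excited = 0.36,
                                                  inhibited = 0.14,
                                                  nonresponsive = 0.50),
                                  amp_hab = 10, amp_cond = 20,
                                  hab_response_prob = 0.5,
                                  rise_s = 0.05, decay_s = 0.5,
                                  noise_sd = 5, sample_rate_hz = 5,
                                  f_rest = 100, amp_latent_sd = 0.3,
                                  amp_jitter = 0.1, us_amp_scale = 1,
                                  seed = 1L) {
  assert_that(length(class_probs) == 3 && abs(sum(class_probs) - 1) < 1e-8 &&
                all(class_probs >= 0),
              "class_probs must be 3 nonnegative probabilities summing to 1")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(amp_hab >= 0 && amp_cond >= 0, "amplitudes must be nonnegative")
  assert_that(hab_response_prob >= 0 && hab_response_prob <= 1,
              "hab_response_prob outside [0, 1]")
  structure(as.list(environment())[c(
    "n_neurons", "class_probs", "amp_hab", "amp_cond", "hab_response_prob",
    "rise_s", "decay_s", "noise_sd", "sample_rate_hz", "f_rest",
    "amp_latent_sd", "amp_jitter", "us_amp_scale", "seed")],
    class = "calcium_cohort_params")
}

#' Generate a synthetic calcium-imaging cohort
#'
#' Simulates one habituation and one conditioning session per neuron from
#' the given schedules. Raw fluorescence is
#' `f_rest * (1 + (signal + noise) / 100)` where the signal is the planted
#' class-signed transient; CS- trials carry no planted response.
#'
#' @param params a [calcium_cohort_params()].
#' @param schedule_hab,schedule_cond [trial_schedule()]s for the two phases.
#' @return A list with `neurons` (per neuron, a list with `hab` and `cond`
#'   trace sets), `truth` (`$neurons`: class, sign and effective amplitudes;
#'   `$trials`: per phase/trial cue and shared amplitude latent) and
#'   `params`.
#' @export
generate_calcium_cohort <- function(params, schedule_hab, schedule_cond) {
  stopifnot(inherits(params, "calcium_cohort_params"),
            inherits(schedule_hab, "trial_schedule"),
            inherits(schedule_cond, "trial_schedule"))
  assert_that(schedule_hab$phase == "habituation" &&
                schedule_cond$phase == "conditioning",
              "schedules must be one habituation and one conditioning session")
  p <- params
  window <- trace_window(p$sample_rate_hz, 5, 15)
  tt <- window_times(window)
  assert_that(5 * p$decay_s < window$total_s - window$pre_s,
              "transient kernel longer than the trial window")
  kern_cue <- transient_kernel(tt, p$rise_s, p$decay_s)
  us_rel <- schedule_hab$cs_duration_s + schedule_hab$us_delay_s  # 1.5 s
  kern_us <- transient_kernel(tt - us_rel, p$rise_s, p$decay_s)

  scheds <- list(habituation = schedule_hab, conditioning = schedule_cond)
  neuron_truth <- with_seed(p$seed, {
    cls <- sample(c("excited", "inhibited", "nonresponsive"), p$n_neurons,
                  replace = TRUE, prob = p$class_probs)
    responds_hab <- stats::runif(p$n_neurons) < p$hab_response_prob
    sign <- ifelse(cls == "excited", 1, ifelse(cls == "inhibited", -1, 0))
    data.frame(neuron_id = sprintf("c%03d", seq_len(p$n_neurons)),
               class = cls, sign = sign,
               amp_hab = ifelse(sign != 0 & responds_hab, p$amp_hab, 0),
               amp_cond = ifelse(sign != 0, p$amp_cond, 0))
  })
  trial_truth <- do.call(rbind, lapply(names(scheds), function(ph) {
    tr <- scheds[[ph]]$trials
    lat <- with_seed(child_seed(p$seed, match(ph, phase_levels) * 100000L), {
      pmax(0, 1 + p$amp_latent_sd * stats::rnorm(nrow(tr)))
    })
    data.frame(phase = ph, trial_index = tr$trial_index, cue = tr$cue,
               paired_us = tr$paired_us, amp_latent = lat)
  }))

  neurons <- vector("list", p$n_neurons)
  for (i in seq_len(p$n_neurons)) {
    sets <- with_seed(child_seed(p$seed, i), {
      lapply(names(scheds), function(ph) {
        sch <- scheds[[ph]]
        tr <- sch$trials
        lat <- trial_truth$amp_latent[trial_truth$phase == ph]
        amp <- if (ph == "habituation") neuron_truth$amp_hab[i]
               else neuron_truth$amp_cond[i]
        s <- neuron_truth$sign[i]
        n_trials <- nrow(tr)
        sig <- matrix(0, n_trials, window$n_samples)
        for (t_i in seq_len(n_trials)) {
          a <- amp * lat[t_i] * (1 + p$amp_jitter * stats::rnorm(1))
          if (tr$cue[t_i] == "CSplus") {
            sig[t_i, ] <- s * a * kern_cue
            if (tr$paired_us[t_i])
              sig[t_i, ] <- sig[t_i, ] + s * a * p$us_amp_scale * kern_us
          } else if (tr$cue[t_i] == "US_unpredicted") {
            # unconditioned response, aligned at the event onset, same sign
            a_us <- p$amp_cond * lat[t_i] * (1 + p$amp_jitter * stats::rnorm(1))
            sig[t_i, ] <- s * a_us * p$us_amp_scale * kern_cue
          }
        }
        noise <- matrix(stats::rnorm(length(sig), 0, p$noise_sd),
                        n_trials, window$n_samples)
        raw <- p$f_rest * (1 + (sig + noise) / 100)
        neuron_trace_set(neuron_truth$neuron_id[i],
                         session_id = paste0(substr(ph, 1, 4), "1"),
                         phase = ph, window = window,
                         cue_per_trial = tr$cue, raw_f = raw)
      })
    })
    names(sets) <- c("hab", "cond")
    neurons[[i]] <- sets
  }
  list(neurons = neurons,
       truth = list(neurons = neuron_truth, trials = trial_truth),
       params = p)
}
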