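#' Parameters for synthetic eyeblink behavior
#'
#' Describes a cohort of mice performing the conditioning task. On CS+
#' trials the eye area drops by a per-trial fractional depth during the
#' conditioned-response window; the mean depth grows from habituation to
#' conditioning for learners and stays at zero for non-learners. CS- trials
#' carry no planted blink. Airpuffs always force a full blink. When
#' `neuron_coupling > 0` the per-trial depth covaries with the shared
#' responsive-neuron activity latent of a calcium cohort, so that
#' trial-by-trial blink strength tracks neural activity (the structure the
#' per-neuron decoder exploits); at coupling 1 with zero blink noise, depth
#' is a strictly increasing function of that latent.
#'
#' @param n_mice number of mice (default 10).
#' @param learner logical; `FALSE` sets both depths to zero.
#' @param cr_depth_hab,cr_depth_cond mean fractional eye closure during the
#'   CR window on CS+ trials per phase, in `[0, 1]` (defaults 0.05, 0.3).
#' @param blink_noise_sd trial-to-trial depth noise SD (default 0.05); half
#'   of it is also applied as per-frame relative area noise.
#' @param neuron_coupling in `[0, 1]`: correlation strength between trial
#'   depth and the calcium cohort's shared trial latent (default 0).
#' @param depth_spread relative modulation of depth by the coupled latent
#'   (default 0.3, matching the calcium generator's latent scale).
#' @param baseline_px baseline eye area, pixels (default 2000).
#' @param seed master seed.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(n_mice = 10, learner = TRUE,
                            cr_depth_hab = 0.05, cr_depth_cond = 0.3,
                            blink_noise_sd = 0.05, neuron_coupling = 0,
                            depth_spread = 0.3, baseline_px = 2000,
                            seed = 1L) {
  assert_that(cr_depth_hab >= 0 && cr_depth_hab <= 1 &&
                cr_depth_cond >= 0 && cr_depth_cond <= 1,
              "CR depths must be in [0, 1]")
  assert_that(neuron_coupling >= 0 && neuron_coupling <= 1,
              "neuron_coupling outside [0, 1]")
  assert_that(blink_noise_sd >= 0, "blink_noise_sd must be nonnegative")
  structure(as.list(environment())[c(
    "n_mice", "learner", "cr_depth_hab", "cr_depth_cond", "blink_noise_sd",
    "neuron_coupling", "depth_spread", "baseline_px", "seed")],
    class = "behavior_params")
}

#' Generate synthetic eyeblink behavior sessions
#'
#' @param params a [behavior_params()].
#' @param schedule_hab,schedule_cond [trial_schedule()]s for the two phases.
#' @param calcium_truth optional `truth` element of a
#'   [generate_calcium_cohort()] result; required when
#'   `params$neuron_coupling > 0` (its shared trial latent drives the
#'   coupled blink depths).
#' @return A list with `mice` (per mouse, a list with `hab` and `cond`
#'   [behavior_session()]s) and `truth` (data frame of planted per-trial
#'   depths).
#' @export
generate_behavior <- function(params, schedule_hab, schedule_cond,
                              calcium_truth = NULL) {
  stopifnot(inherits(params, "behavior_params"))
  p <- params
  if (p$neuron_coupling > 0)
    assert_that(!is.null(calcium_truth),
                "neuron_coupling > 0 requires calcium_truth")
  scheds <- list(habituation = schedule_hab, conditioning = schedule_cond)
  window <- trace_window(10, 5, 15)
  tt <- window_times(window)
  cr_frames <- tt >= 0 & tt < 1.5
  depths <- list(habituation = if (p$learner) p$cr_depth_hab else 0,
                 conditioning = if (p$learner) p$cr_depth_cond else 0)
  latent_std <- function(ph, n) {
    if (is.null(calcium_truth)) return(rep(0, n))
    lat <- calcium_truth$trials$amp_latent[calcium_truth$trials$phase == ph]
    assert_that(length(lat) == n, "calcium truth trials do not match schedule")
    as.numeric(scale(lat))
  }
  truth_rows <- list()
  mice <- vector("list", p$n_mice)
  for (m in seq_len(p$n_mice)) {
    sets <- with_seed(child_seed(p$seed, m), {
      lapply(names(scheds), function(ph) {
        sch <- scheds[[ph]]
        tr <- sch$trials
        n_trials <- nrow(tr)
        a_std <- latent_std(ph, n_trials)
        eta <- stats::rnorm(n_trials)
        d <- rep(0, n_trials)
        plus <- tr$cue == "CSplus"
        d[plus] <- pmin(1, pmax(0,
          depths[[ph]] * (1 + p$depth_spread * p$neuron_coupling * a_std[plus]) +
            p$blink_noise_sd * sqrt(1 - p$neuron_coupling^2) * eta[plus]))
        frame_noise <- 0.5 * p$blink_noise_sd
        area <- matrix(p$baseline_px, n_trials, window$n_samples)
        if (frame_noise > 0)
          area <- area * (1 + frame_noise *
                            matrix(stats::rnorm(length(area)), nrow(area)))
        for (t_i in seq_len(n_trials)) {
          if (plus[t_i])
            area[t_i, cr_frames] <- area[t_i, cr_frames] * (1 - d[t_i])
          # airpuff forces a full blink
          us_rel <- if (tr$paired_us[t_i]) sch$cs_duration_s + sch$us_delay_s
                    else if (tr$cue[t_i] == "US_unpredicted") 0 else NA
          if (!is.na(us_rel)) {
            usf <- tt >= us_rel & tt < us_rel + sch$us_duration_s
            area[t_i, usf] <- 0.05 * p$baseline_px
          }
        }
        area <- pmax(area, 1)
        truth_rows[[length(truth_rows) + 1]] <<-
          data.frame(mouse = m, phase = ph, trial_index = tr$trial_index,
                     cue = tr$cue, depth = d)
        behavior_session(sprintf("m%02d", m), ph, tr$cue, area, window)
      })
    })
    names(sets) <- c("hab", "cond")
    mice[[m]] <- sets
  }
  list(mice = mice, truth = do.call(rbind, truth_rows), params = p)
}
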