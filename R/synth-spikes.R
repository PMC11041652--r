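#' Parameters for a synthetic foot-shock spike cohort
#'
#' Describes a cohort of spontaneously firing neurons receiving repeated
#' foot shocks. Baseline rates are log-normal; each neuron's foot-shock
#' modulation is tied to its baseline rate through a Gaussian copula at
#' correlation `coupling_rho`, reproducing the anticorrelation between
#' spontaneous rate and foot-shock modulation that the classification
#' stage is meant to detect. Classes (excited / inhibited / non-modulated)
#' are assigned by thresholding the copula's modulation coordinate at the
#' planted proportions, and within each class the planted modulation index
#' spreads monotonically around `(effect_ratio - 1) / (effect_ratio + 1)`.
#'
#' @param n_neurons cohort size.
#' @param rate_median_hz median of the log-normal baseline-rate
#'   distribution, Hz (default 5).
#' @param rate_sigma log-scale standard deviation (default 0.8).
#' @param coupling_rho target correlation in `[-1, 0]` between log baseline
#'   rate and planted modulation (default -0.5).
#' @param frac_excited,frac_inhibited,frac_nonmod class proportions, must
#'   sum to 1 (defaults 0.68 / 0.19 / 0.13).
#' @param effect_ratio multiplicative firing-rate change during the 1-s
#'   post-shock window for a mid-class neuron; rates are multiplied by the
#'   per-neuron ratio for excited neurons and divided for inhibited ones.
#'   `effect_ratio = 1` plants a null cohort.
#' @param effect_spread relative within-class spread of the planted
#'   modulation index (default 0.5, i.e. 50-150 percent of the class base).
#' @param burst_prob probability that a spike seeds a short burst of 2-4
#'   extra spikes at 5-15 ms lags (default 0.15).
#' @param gamma_shape shape of the gamma-renewal inter-spike intervals
#'   (1 = Poisson; >1 more regular).
#' @param n_fs_trials number of foot-shock trials (default 40).
#' @param fs_iti_s foot-shock inter-stimulus interval, seconds (5).
#' @param fs_duration_s shock duration, seconds (0.5).
#' @param duration_s spontaneous epoch length before stimulation, seconds
#'   (default 300).
#' @param seed master seed; per-neuron seeds are derived by a fixed counter
#'   scheme so the cohort is fully reproducible.
#' @return An object of class `spike_cohort_params`.
#' @export
spike_cohort_params <- function(n_neurons = 200, rate_median_hz = 5,
                                rate_sigma = 0.8, coupling_rho = -0.5,
                                frac_excited = 0.68, frac_inhibited = 0.19,
                                frac_nonmod = 0.13, effect_ratio = 3,
                                effect_spread = 0.5, burst_prob = 0.15,
                                gamma_shape = 1, n_fs_trials = 40,
                                fs_iti_s = 5, fs_duration_s = 0.5,
                                duration_s = 300, seed = 1L) {
  fr <- c(frac_excited, frac_inhibited, frac_nonmod)
  assert_that(abs(sum(fr) - 1) < 1e-8 && all(fr >= 0),
              "class proportions must be nonnegative and sum to 1")
  assert_that(effect_ratio > 0, "effect_ratio must be positive")
  assert_that(n_fs_trials >= 1, "need at least one foot-shock trial")
  assert_that(coupling_rho >= -1 && coupling_rho <= 1, "coupling_rho outside [-1, 1]")
  if (coupling_rho != 0 && frac_excited + frac_inhibited == 0)
    stop_pavcond("infeasible coupling: nonzero coupling_rho with no modulated class")
  assert_that(burst_prob >= 0 && burst_prob <= 1, "burst_prob outside [0, 1]")
  structure(as.list(environment())[c(
    "n_neurons", "rate_median_hz", "rate_sigma", "coupling_rho",
    "frac_excited", "frac_inhibited", "frac_nonmod", "effect_ratio",
    "effect_spread", "burst_prob", "gamma_shape", "n_fs_trials",
    "fs_iti_s", "fs_duration_s", "duration_s", "seed")],
    class = "spike_cohort_params")
}

# Gamma-renewal spike train with a piecewise-constant rate, simulated by
# time rescaling: unit-rate renewal arrivals are mapped through the inverse
# cumulative rate.
sim_renewal_train <- function(bounds, rates, shape) {
  seg_len <- diff(bounds)
  seg_mass <- seg_len * rates
  cum_mass <- c(0, cumsum(seg_mass))
  total <- cum_mass[length(cum_mass)]
  if (total <= 0) return(numeric())
  arrivals <- numeric()
  last <- 0
  repeat {
    k <- max(50, ceiling(total - last + 6 * sqrt(total + 1)))
    draw <- cumsum(stats::rgamma(k, shape = shape, rate = shape)) + last
    arrivals <- c(arrivals, draw[draw <= total])
    last <- draw[length(draw)]
    if (last > total) break
  }
  seg <- findInterval(arrivals, cum_mass, rightmost.closed = TRUE)
  seg[seg > length(rates)] <- length(rates)
  bounds[seg] + (arrivals - cum_mass[seg]) / rates[seg]
}

#' Generate a synthetic foot-shock spike cohort
#'
#' Simulates every neuron described by `params` and returns the recordings
#' together with a ground-truth table sufficient to score classification
#' and correlation recovery. Spontaneous spiking is a gamma-renewal process
#' with burst riders; during each 1-s post-shock window the rate is
#' multiplied by the neuron's planted effect ratio.
#'
#' @param params a [spike_cohort_params()].
#' @return A list with elements `recordings` (list of spike trains),
#'   `truth` (data frame: `neuron_id`, `class`, `baseline_rate_hz`,
#'   `true_mod`, `effect_ratio`) and `params`.
#' @export
generate_spike_cohort <- function(params) {
  stopifnot(inherits(params, "spike_cohort_params"))
  p <- params
  truth <- with_seed(p$seed, {
    z_rate <- stats::rnorm(p$n_neurons)
    z_mod <- p$coupling_rho * z_rate +
      sqrt(1 - p$coupling_rho^2) * stats::rnorm(p$n_neurons)
    rates <- exp(log(p$rate_median_hz) + p$rate_sigma * z_rate)
    n_inh <- round(p$frac_inhibited * p$n_neurons)
    n_exc <- round(p$frac_excited * p$n_neurons)
    cls <- rep("non_modulated", p$n_neurons)
    ord <- order(z_mod)
    if (n_inh > 0) cls[ord[seq_len(n_inh)]] <- "FS_inhibited"
    if (n_exc > 0) cls[ord[seq(p$n_neurons - n_exc + 1, p$n_neurons)]] <- "FS_excited"
    m_base <- (p$effect_ratio - 1) / (p$effect_ratio + 1)
    m <- numeric(p$n_neurons)
    for (k in c("FS_excited", "FS_inhibited")) {
      idx <- which(cls == k)
      if (!length(idx)) next
      u <- (rank(z_mod[idx]) - 0.5) / length(idx)
      m[idx] <- if (k == "FS_excited")
        m_base * (1 + p$effect_spread * (2 * u - 1))
      else
        -m_base * (1 + p$effect_spread * (1 - 2 * u))
    }
    data.frame(neuron_id = sprintf("n%03d", seq_len(p$n_neurons)),
               class = cls, baseline_rate_hz = rates, true_mod = m,
               effect_ratio = (1 + m) / (1 - m))
  })
  fs_onsets <- p$duration_s + p$fs_iti_s * seq_len(p$n_fs_trials)
  total_dur <- p$duration_s + p$fs_iti_s * p$n_fs_trials + 2
  # piecewise-constant rate: baseline everywhere, scaled in 1-s post-onset windows
  bounds <- sort(unique(c(0, fs_onsets, fs_onsets + 1, total_dur)))
  in_fs <- vapply(bounds[-length(bounds)], function(b)
    any(b >= fs_onsets - 1e-12 & b < fs_onsets + 1), logical(1))
  recordings <- vector("list", p$n_neurons)
  for (i in seq_len(p$n_neurons)) {
    recordings[[i]] <- with_seed(child_seed(p$seed, i), {
      r <- truth$baseline_rate_hz[i]
      seg_rates <- ifelse(in_fs, r * truth$effect_ratio[i], r)
      st <- sim_renewal_train(bounds, seg_rates, p$gamma_shape)
      if (p$burst_prob > 0 && length(st)) {
        seeds_burst <- which(stats::runif(length(st)) < p$burst_prob)
        extras <- unlist(lapply(st[seeds_burst], function(t0) {
          k <- sample(2:4, 1)
          t0 + cumsum(stats::runif(k, 0.005, 0.015))
        }))
        st <- sort(c(st, extras))
      }
      st <- st[st >= 0 & st <= total_dur]
      if (length(st) > 1) st <- st[c(TRUE, diff(st) >= 0.001)]  # refractory
      spike_train_recording(truth$neuron_id[i], st, total_dur,
                            fs_onsets, p$fs_duration_s)
    })
  }
  list(recordings = recordings, truth = truth, params = p)
}
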