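# Fiber-photometry photon-count analysis: smoothing, trial dF/F0 and peak
# extraction, the signal-validity criterion, 5-trial binned peak means and
# the cue-by-bin comparison.

#' Photometry analysis configuration
#'
#' @param smooth_window running-average window in samples (default 10).
#' @param epoch_s validity epoch length, seconds (default 0.05).
#' @param sd_multiplier threshold in baseline SDs (default 2).
#' @param min_epochs epochs beyond threshold needed for a valid signal
#'   (default 3).
#' @param f0_window_s pre-event F0 window, seconds (default 3).
#' @param peak_window_s response window for peak extraction, seconds
#'   (default `c(0, 1.5)`).
#' @param bin_trials trials per bin for binned peak means (default 5).
#' @return An object of class `photometry_config`.
#' @export
photometry_config <- function(smooth_window = 10, epoch_s = 0.05,
                              sd_multiplier = 2, min_epochs = 3,
                              f0_window_s = 3, peak_window_s = c(0, 1.5),
                              bin_trials = 5) {
  assert_that(smooth_window >= 1, "smooth_window must be >= 1")
  assert_that(epoch_s > 0 && sd_multiplier > 0 && min_epochs >= 1 &&
                f0_window_s > 0 && bin_trials >= 1,
              "photometry config values must be positive")
  resp_len <- peak_window_s[2] - peak_window_s[1]
  assert_that(abs(resp_len / epoch_s - round(resp_len / epoch_s)) < 1e-9,
              "epoch length must divide the response window evenly")
  structure(list(smooth_window = as.integer(smooth_window),
                 epoch_s = epoch_s, sd_multiplier = sd_multiplier,
                 min_epochs = as.integer(min_epochs),
                 f0_window_s = f0_window_s,
                 peak_window_s = as.numeric(peak_window_s),
                 bin_trials = as.integer(bin_trials)),
            class = "photometry_config")
}

#' Running-average smoothing of a photon-count series
#'
#' Centered moving average with edge truncation: near the series ends the
#' window shrinks to the available samples, so the output has the input's
#' length. A trailing (causal) window is available behind
#' `align = "trailing"`.
#'
#' @param counts numeric series.
#' @param window window length in samples (default 10).
#' @param align `"centered"` (default) or `"trailing"`.
#' @return Smoothed series, same length.
#' @export
smooth_counts <- function(counts, window = 10, align = c("centered", "trailing")) {
  align <- match.arg(align)
  n <- length(counts)
  assert_that(window >= 1, "window must be >= 1")
  assert_that(window <= n, "window (%d) longer than series (%d)", window, n)
  if (window == 1) return(as.numeric(counts))
  cs <- cumsum(c(0, counts))
  i <- seq_len(n)
  if (align == "centered") {
    lo <- pmax(1, i - floor(window / 2))
    hi <- pmin(n, i + ceiling(window / 2) - 1)
  } else {
    lo <- pmax(1, i - window + 1)
    hi <- i
  }
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Trial dF/F0 and peak responses of a photometry series
#'
#' Smooths the photon counts, aligns a 15-s trial window (5 s pre-event)
#' around every event, computes percent dF/F0 per trial with `F0` the mean
#' smoothed count over the 3 s preceding the event (for unpredicted
#' airpuffs the window is anchored at the airpuff onset), and extracts the
#' peak dF/F0 over the response window.
#'
#' @param series a [photometry_series()].
#' @param cfg a [photometry_config()].
#' @return A data frame of class `sensor_trial_response` with one row per
#'   event: `onset_s`, `cue`, `phase`, `trial` (ordinal within phase x
#'   cue), `peak`; the trial dF/F0 matrix is in attribute `dff`, the trial
#'   window in attribute `window`.
#' @export
photometry_dff <- function(series, cfg = photometry_config()) {
  stopifnot(inherits(series, "photometry_series"))
  sm <- smooth_counts(series$counts, cfg$smooth_window)
  rate <- 1 / series$bin_width_s
  w <- trace_window(rate, 5, 15)
  ev <- series$events
  mat <- align_trials(sm, ev$onset_s, w, on_edge = "drop")
  kept <- attr(mat, "kept")
  ev <- ev[kept, , drop = FALSE]
  tt <- window_times(w)
  f0w <- tt >= -cfg$f0_window_s & tt < 0
  f0 <- rowMeans(mat[, f0w, drop = FALSE])
  bad <- !(f0 > 0)
  if (any(bad))
    warning(sprintf("%d trial(s) with zero-count baseline flagged invalid",
                    sum(bad)), call. = FALSE)
  dff <- 100 * sweep(mat, 1, f0, "-") / f0
  dff[bad, ] <- NA_real_
  pk <- tt >= cfg$peak_window_s[1] & tt < cfg$peak_window_s[2]
  out <- data.frame(onset_s = ev$onset_s, cue = ev$cue, phase = ev$phase,
                    peak = apply(dff[, pk, drop = FALSE], 1, function(z)
                      if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)))
  out$trial <- stats::ave(seq_len(nrow(out)),
                          paste(out$phase, out$cue), FUN = seq_along)
  attr(out, "dff") <- dff
  attr(out, "window") <- w
  class(out) <- c("sensor_trial_response", "data.frame")
  out
}

# Epoch means of the response span of an averaged trace.
epoch_means <- function(avg_trace, tt, cfg) {
  resp <- which(tt >= cfg$peak_window_s[1] & tt < cfg$peak_window_s[2])
  per <- round(cfg$epoch_s * length(tt) /
                 (tt[length(tt)] - tt[1] + (tt[2] - tt[1])))
  n_ep <- floor(length(resp) / per)
  vapply(seq_len(n_ep), function(e)
    mean(avg_trace[resp[((e - 1) * per + 1):(e * per)]]), numeric(1))
}

#' Signal-validity criterion for a trial-averaged response
#'
#' Decides whether an averaged smoothed photon-count trace contains a real
#' photometric response: the baseline mean and SD are computed over the
#' pre-event span (3 s before onset), the response span (0-1.5 s) is cut
#' into consecutive 50-ms epochs, and the signal is valid when at least
#' `min_epochs` epoch means lie above `baseline + 2 SD` or below
#' `baseline - 2 SD` (epochs need not be consecutive). A constant trace
#' (zero baseline SD) is flagged degenerate and is valid iff any epoch
#' differs from baseline at all.
#'
#' @param avg_response trial-averaged smoothed counts on the trial axis.
#' @param window the trial [trace_window()].
#' @param cfg a [photometry_config()].
#' @return A list with `valid`, `responsive_epochs` (indices),
#'   `n_epochs`, `baseline_mean`, `baseline_sd`, `degenerate`.
#' @export
signal_validity <- function(avg_response, window, cfg = photometry_config()) {
  tt <- window_times(window)
  basei <- tt >= -cfg$f0_window_s & tt < 0
  assert_that(any(basei), "no baseline span in the averaged trace")
  b_mean <- mean(avg_response[basei])
  b_sd <- stats::sd(avg_response[basei])
  per <- round(cfg$epoch_s * window$sample_rate_hz)
  resp <- which(tt >= cfg$peak_window_s[1] & tt < cfg$peak_window_s[2])
  n_ep <- floor(length(resp) / per)
  assert_that(n_ep >= cfg$min_epochs,
              "response span too short for %d epochs", cfg$min_epochs)
  em <- vapply(seq_len(n_ep), function(e)
    mean(avg_response[resp[((e - 1) * per + 1):(e * per)]]), numeric(1))
  degenerate <- !(b_sd > 0)
  if (degenerate) {
    hits <- which(abs(em - b_mean) > 0)
    valid <- length(hits) > 0
  } else {
    hits <- which(em > b_mean + cfg$sd_multiplier * b_sd |
                    em < b_mean - cfg$sd_multiplier * b_sd)
    valid <- length(hits) >= cfg$min_epochs
  }
  list(valid = valid, responsive_epochs = hits, n_epochs = n_ep,
       baseline_mean = b_mean, baseline_sd = b_sd, degenerate = degenerate)
}

#' Assess an animal's signal validity from its habituation session
#'
#' Applies [signal_validity()] to the habituation trial-averaged smoothed
#' response for each stimulus (CS+, CS-, unpredicted airpuff); the animal
#' is valid when any stimulus passes.
#'
#' @param series a [photometry_series()].
#' @param cfg a [photometry_config()].
#' @return A list with `valid` and `per_stimulus` (named list of
#'   [signal_validity()] reports).
#' @export
assess_signal_validity <- function(series, cfg = photometry_config()) {
  stopifnot(inherits(series, "photometry_series"))
  sm <- smooth_counts(series$counts, cfg$smooth_window)
  w <- trace_window(1 / series$bin_width_s, 5, 15)
  ev <- series$events[series$events$phase == "habituation", , drop = FALSE]
  assert_that(nrow(ev) > 0, "no habituation events in series")
  reports <- lapply(split(ev$onset_s, ev$cue), function(onsets) {
    mat <- align_trials(sm, onsets, w, on_edge = "drop")
    if (nrow(mat) == 0) return(NULL)
    signal_validity(colMeans(mat), w, cfg)
  })
  reports <- Filter(Negate(is.null), reports)
  list(valid = any(vapply(reports, `[[`, logical(1), "valid")),
       per_stimulus = reports)
}

#' Binned peak responses
#'
#' Groups trials by phase and cue in their session order, cuts them into
#' consecutive non-overlapping bins of `bin_trials` trials, and averages
#' the peak dF/F0 per bin. A trailing partial bin is kept and flagged.
#'
#' @param responses a [photometry_dff()] result (or any data frame with
#'   `phase`, `cue`, `trial`, `peak`).
#' @param cfg a [photometry_config()].
#' @return Data frame with `phase`, `cue`, `bin_index`, `mean_peak`,
#'   `n_trials`, `partial`.
#' @export
binned_peak_responses <- function(responses, cfg = photometry_config()) {
  need <- c("phase", "cue", "trial", "peak")
  assert_that(all(need %in% names(responses)),
              "responses need columns: %s", paste(need, collapse = ", "))
  parts <- split(as.data.frame(responses)[need],
                 list(responses$phase, responses$cue), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$trial), ]
    bin <- ceiling(seq_len(nrow(d)) / cfg$bin_trials)
    agg <- vapply(split(d$peak, bin), mean, numeric(1), na.rm = TRUE)
    ns <- vapply(split(d$peak, bin), length, integer(1))
    data.frame(phase = d$phase[1], cue = d$cue[1],
               bin_index = as.integer(names(agg)), mean_peak = unname(agg),
               n_trials = unname(ns),
               partial = unname(ns) < cfg$bin_trials)
  }))
  rownames(out) <- NULL
  out[order(out$phase, out$cue, out$bin_index), ]
}

#' Cue effect on binned peak responses
#'
#' Two-factor analysis of variance (cue x trial bin) on the binned mean
#' peaks of one phase, pooled across animals; reports the cue main effect
#' (the learning-dependent cue discrimination statistic for a sensor).
#'
#' @param binned a [binned_peak_responses()] table, possibly row-bound
#'   across animals; only CS+ and CS- rows of `phase` are used.
#' @param phase phase to test (default `"conditioning"`).
#' @return A list with `F`, `df`, `p_value` and the per-cue means.
#' @export
cue_effect_test <- function(binned, phase = "conditioning") {
  d <- binned[binned$phase == phase & binned$cue %in% c("CSplus", "CSminus"), ]
  assert_that(nrow(d) > 0, "no cue bins for phase %s", phase)
  tab <- table(d$cue)
  assert_that(length(tab) == 2, "both cues must be present")
  assert_that(length(unique(d$bin_index)) >= 2, "need at least 2 bins per cue")
  d$cue <- factor(d$cue, levels = c("CSminus", "CSplus"))
  d$bin <- factor(d$bin_index)
  if (stats::sd(d$mean_peak) == 0) {
    return(list(F = 0, df = c(1, nrow(d) - 2), p_value = 1,
                mean_csplus = mean(d$mean_peak[d$cue == "CSplus"]),
                mean_csminus = mean(d$mean_peak[d$cue == "CSminus"])))
  }
  fit <- stats::aov(mean_peak ~ cue * bin, data = d)
  an <- summary(fit)[[1]]
  if (!"Residuals" %in% trimws(rownames(an)) ||
      an[nrow(an), "Df"] == 0 || fit$df.residual == 0) {
    # one observation per cue x bin cell: interaction saturates, drop it
    fit <- stats::aov(mean_peak ~ cue + bin, data = d)
    an <- summary(fit)[[1]]
  }
  i <- match("cue", trimws(rownames(an)))
  # exactly cue-symmetric data: both cue and residual sums of squares are
  # numerical zeros and the F ratio is 0/0 noise; report F = 0, p = 1
  if (an[i, "Sum Sq"] <= 1e-10 * sum(an[, "Sum Sq"]))
    return(list(F = 0, df = c(an[i, "Df"], an[nrow(an), "Df"]), p_value = 1,
                mean_csplus = mean(d$mean_peak[d$cue == "CSplus"]),
                mean_csminus = mean(d$mean_peak[d$cue == "CSminus"])))
  list(F = an[i, "F value"], df = c(an[i, "Df"], an[nrow(an), "Df"]),
       p_value = an[i, "Pr(>F)"],
       mean_csplus = mean(d$mean_peak[d$cue == "CSplus"]),
       mean_csminus = mean(d$mean_peak[d$cue == "CSminus"]))
}
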