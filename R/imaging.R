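# Trial-aligned dF/F0, AUC response classification, plasticity
# contingency, and histological relative fluorescence.

#' Compute trial-by-trial percent dF/F0
#'
#' `dF/F0 = 100 * (F - F0) / F0` per trial, with `F0` the mean raw
#' fluorescence over the `dff_f0_window_s` seconds (default 3) preceding
#' cue onset. Trials with non-positive `F0` are flagged invalid (rows set
#' to `NA`, indices in attribute `invalid_trials`).
#'
#' @param traces a [neuron_trace_set()].
#' @param cfg an [analysis_config()].
#' @return The trace set with `dff_pct` filled in.
#' @export
compute_dff <- function(traces, cfg = analysis_config()) {
  stopifnot(inherits(traces, "trace_set"))
  tt <- window_times(traces$window)
  f0w <- tt >= -cfg$dff_f0_window_s & tt < 0
  assert_that(any(f0w), "F0 window has no samples")
  f0 <- rowMeans(traces$raw_f[, f0w, drop = FALSE])
  bad <- !(f0 > 0)
  if (any(bad))
    warning(sprintf("%d trial(s) with non-positive F0 flagged invalid",
                    sum(bad)), call. = FALSE)
  dff <- 100 * sweep(traces$raw_f, 1, f0, "-") / f0
  dff[bad, ] <- NA_real_
  out <- neuron_trace_set(traces$neuron_id, traces$session_id, traces$phase,
                          traces$window, traces$cue_per_trial, traces$raw_f,
                          dff_pct = dff)
  attr(out, "invalid_trials") <- which(bad)
  out
}

#' Area under the curve of a trial trace over a window
#'
#' Trapezoidal integral of a dF/F0 trace (percent) over `[start, end]`
#' seconds on the trial time axis, with the trace linearly interpolated at
#' the window edges so the integral spans the full window length.
#'
#' @param dff_trial numeric trace of one trial.
#' @param window numeric `c(start_s, end_s)` on the trial axis.
#' @param trace_window the trial's [trace_window()].
#' @return AUC in percent-seconds.
#' @export
trial_window_auc <- function(dff_trial, window, trace_window) {
  tt <- window_times(trace_window)
  trapz_window(dff_trial, tt, window)
}

#' Classify a neuron's cue or airpuff response
#'
#' Per trial of the requested cue, compares the baseline AUC against the
#' response AUC with a Wilcoxon rank-sum test (signed-rank behind
#' `paired = TRUE`). For the anticipatory response the window is
#' cue onset to airpuff onset (0-1.5 s) against the 1.5-s baseline ending
#' at cue onset; for the airpuff response the window is the 0.5-s airpuff
#' epoch against a duration-matched baseline ending at cue onset. The
#' class is `excited` / `inhibited` when `p <= alpha` with the sign of
#' `median(response) - median(baseline)`, else `nonresponsive`.
#'
#' @param neuron a [neuron_trace_set()] (dF/F0 computed on demand).
#' @param cue cue label to analyze (default `"CSplus"`).
#' @param response `"anticipatory"` or `"us"`.
#' @param cfg an [analysis_config()].
#' @param min_trials minimum trials of the cue required (default 5).
#' @param paired use the signed-rank variant.
#' @param us_onset_s airpuff onset on the trial axis for `response="us"`
#'   (default 1.5; use 0 for trials aligned at an unpredicted airpuff).
#' @param us_duration_s airpuff epoch length, seconds (default 0.5).
#' @return An object of class `window_response` with per-trial AUC pairs,
#'   the p-value and the class.
#' @export
classify_cue_response <- function(neuron, cue = "CSplus",
                                  response = c("anticipatory", "us"),
                                  cfg = analysis_config(), min_trials = 5,
                                  paired = FALSE, us_onset_s = 1.5,
                                  us_duration_s = 0.5) {
  stopifnot(inherits(neuron, "trace_set"))
  response <- match.arg(response)
  if (is.null(neuron$dff_pct)) neuron <- compute_dff(neuron, cfg)
  idx <- which(neuron$cue_per_trial == cue)
  if (length(idx) < min_trials)
    stop_pavcond("neuron %s excluded: %d %s trials (need >= %d)",
                 neuron$neuron_id, length(idx), cue, min_trials)
  if (response == "anticipatory") {
    resp_win <- c(0, cfg$cr_window[2])
    base_win <- c(-cfg$imaging_baseline_window_s, 0)
  } else {
    resp_win <- c(us_onset_s, us_onset_s + us_duration_s)
    base_win <- c(-us_duration_s, 0)
  }
  dff <- neuron$dff_pct[idx, , drop = FALSE]
  ok <- stats::complete.cases(dff)
  dff <- dff[ok, , drop = FALSE]
  assert_that(nrow(dff) >= min_trials,
              "neuron %s: too few valid trials after F0 screening", neuron$neuron_id)
  auc_b <- apply(dff, 1, trial_window_auc, window = base_win,
                 trace_window = neuron$window)
  auc_r <- apply(dff, 1, trial_window_auc, window = resp_win,
                 trace_window = neuron$window)
  if (all(auc_r == auc_b)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(auc_r, auc_b, paired = paired, exact = FALSE)$p.value)
  }
  klass <- "nonresponsive"
  if (!is.na(p) && p <= cfg$alpha) {
    d <- stats::median(auc_r) - stats::median(auc_b)
    if (d > 0) klass <- "excited" else if (d < 0) klass <- "inhibited"
  }
  structure(list(neuron_id = neuron$neuron_id, cue = cue,
                 response = response,
                 auc_baseline = auc_b, auc_window = auc_r,
                 p_value = p, klass = klass,
                 n_trials = nrow(dff)),
            class = "window_response")
}

#' @export
print.window_response <- function(x, ...) {
  cat(sprintf("%s (%s, %s): %s (p = %.3g, %d trials)\n",
              x$neuron_id, x$cue, x$response, x$klass, x$p_value, x$n_trials))
  invisible(x)
}

response_classes <- c("inhibited", "nonresponsive", "excited")

count_classes <- function(x) {
  x <- factor(as.character(x), levels = response_classes)
  table(x)
}

#' Plasticity contingency test across learning
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 3 table
#' of response-class counts in habituation versus conditioning. Only
#' longitudinally tracked neurons (classified in both phases) should be
#' supplied. A class empty in both phases is dropped with a warning and
#' the degrees of freedom adjust accordingly.
#'
#' @param hab_classes,cond_classes character vectors of per-neuron classes
#'   (`"inhibited"`, `"nonresponsive"`, `"excited"`), or named counts.
#' @return An object of class `plasticity_table`: the counts, chi-squared
#'   statistic, degrees of freedom and p-value.
#' @export
plasticity_contingency <- function(hab_classes, cond_classes) {
  to_counts <- function(x) {
    if (is.table(x) || (!is.null(names(x)) && is.numeric(x))) {
      out <- stats::setNames(rep(0, 3), response_classes)
      out[names(x)] <- as.numeric(x)
      out
    } else as.numeric(count_classes(x))
  }
  counts <- rbind(habituation = to_counts(hab_classes),
                  conditioning = to_counts(cond_classes))
  colnames(counts) <- response_classes
  assert_that(all(rowSums(counts) > 0), "a phase has no classified neurons")
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning(sprintf("dropping class column(s) empty in both phases: %s",
                    paste(response_classes[empty], collapse = ", ")),
            call. = FALSE)
    counts_used <- counts[, !empty, drop = FALSE]
  } else counts_used <- counts
  if (ncol(counts_used) < 2 ||
      isTRUE(all.equal(counts_used[1, ] / sum(counts_used[1, ]),
                       counts_used[2, ] / sum(counts_used[2, ])))) {
    chi2 <- 0; df <- ncol(counts_used) - 1; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts_used, correct = FALSE))
    chi2 <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  }
  structure(list(counts = counts, chi2 = chi2, df = df, p_value = p),
            class = "plasticity_table")
}

#' @export
print.plasticity_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("chi-squared = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Relative arbitrary fluorescence of a labeled region
#'
#' Normalized difference `(signal - background) / (signal + background)`
#' between a region's mean intensity and a background region, in
#' `[-1, 1]` for nonnegative intensities.
#'
#' @param signal,background mean intensities, arbitrary units (nonnegative,
#'   not both zero).
#' @return An object of class `region_fluorescence` with `signal`,
#'   `background` and `raf`.
#' @examples
#' relative_fluorescence(300, 100)$raf  # 0.5
#' @export
relative_fluorescence <- function(signal, background) {
  assert_that(is_scalar_number(signal) && is_scalar_number(background),
              "intensities must be single numbers")
  assert_that(signal >= 0 && background >= 0, "intensities must be nonnegative")
  assert_that(signal + background > 0, "signal and background are both zero")
  structure(list(signal = signal, background = background,
                 raf = (signal - background) / (signal + background)),
            class = "region_fluorescence")
}
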