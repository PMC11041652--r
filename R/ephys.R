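# Spike-train featurization and foot-shock response classification.

# Spontaneous segments: recording time minus the 1-s post-onset foot-shock
# response windows. Returns a 2-column matrix of [start, end) intervals.
spontaneous_segments <- function(rec, fs_window_s = 1) {
  if (rec$n_fs_trials == 0)
    return(matrix(c(0, rec$duration_s), 1, 2))
  cuts <- cbind(rec$fs_event_times_s, pmin(rec$fs_event_times_s + fs_window_s,
                                           rec$duration_s))
  starts <- c(0, cuts[, 2])
  ends <- c(cuts[, 1], rec$duration_s)
  keep <- ends > starts + 1e-12
  cbind(starts[keep], ends[keep])
}

acg_counts <- function(st, max_lag_s, bin_s) {
  n_bins <- round(max_lag_s / bin_s)
  if (length(st) < 2) return(rep(0, n_bins))
  hi <- findInterval(st + max_lag_s, st)
  lags <- unlist(lapply(seq_along(st), function(i) {
    if (hi[i] > i) st[(i + 1):hi[i]] - st[i] else numeric()
  }))
  lags <- lags[lags > 0 & lags <= max_lag_s]
  # epsilon guards against floating-point drift at exact bin boundaries
  tabulate(pmin(n_bins, ceiling(lags / bin_s - 1e-9)), nbins = n_bins)
}

#' Spontaneous-activity features of a spike train
#'
#' Computes the spontaneous firing statistics used for embedding: mean
#' firing rate, coefficient of variation of the inter-spike intervals
#' (ISI SD / mean ISI), burst index (fraction of ISIs below 25 ms), a
#' 100-bin ISI histogram (10-ms bins over 0-1 s, normalized to sum to 1),
#' and autocorrelograms at 1-ms resolution over 1-500 ms and 1-100 ms
#' (normalized by spike count). The 1-s post-onset window of every foot
#' shock is excised from the spontaneous statistics, and ISIs are never
#' taken across an excised window.
#'
#' @param rec a [spike_train_recording()].
#' @return An object of class `spike_features`.
#' @export
spike_train_features <- function(rec) {
  stopifnot(inherits(rec, "spike_train"))
  segs <- spontaneous_segments(rec)
  st <- rec$spike_times_s
  # segments are half-open except at the recording end, where a spike at
  # exactly `duration_s` still belongs to the recording
  ends <- segs[, 2]
  ends[ends >= rec$duration_s - 1e-12] <- rec$duration_s + 1e-9
  seg_spikes <- lapply(seq_len(nrow(segs)), function(i)
    st[st >= segs[i, 1] & st < ends[i]])
  n_spont <- sum(lengths(seg_spikes))
  spont_dur <- sum(segs[, 2] - segs[, 1])
  assert_that(n_spont >= 2,
              "insufficient data: %d spontaneous spikes (need >= 2)", n_spont)
  isis <- unlist(lapply(seg_spikes, function(s) if (length(s) > 1) diff(s) else numeric()))
  assert_that(length(isis) >= 1, "insufficient data: no spontaneous ISIs")
  isi_in <- isis[isis <= 1]
  isi_hist <- tabulate(pmin(100, ceiling(isi_in / 0.01 - 1e-9)), nbins = 100)
  if (sum(isi_hist) > 0) isi_hist <- isi_hist / sum(isi_hist)
  # ACGs on spikes within spontaneous segments, per segment so lags never
  # bridge an excised foot-shock window
  acg500 <- Reduce(`+`, lapply(seg_spikes, acg_counts, max_lag_s = 0.5,
                               bin_s = 0.001))
  acg100 <- Reduce(`+`, lapply(seg_spikes, acg_counts, max_lag_s = 0.1,
                               bin_s = 0.001))
  structure(list(neuron_id = rec$neuron_id,
                 firing_rate_hz = n_spont / spont_dur,
                 cv = stats::sd(isis) / mean(isis),
                 burst_index = mean(isis < 0.025),
                 isi_hist = isi_hist,
                 acg_500 = acg500 / n_spont,
                 acg_100 = acg100 / n_spont),
            class = "spike_features")
}

#' @export
print.spike_features <- function(x, ...) {
  cat(sprintf("Spike features %s: rate %.2f Hz, CV %.2f, burst index %.3f\n",
              x$neuron_id, x$firing_rate_hz, x$cv, x$burst_index))
  invisible(x)
}

pca_scores <- function(M, k, label) {
  M <- as.matrix(M)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  avail <- min(k, ncol(pc$x))
  out <- matrix(0, nrow(M), k)
  out[, seq_len(avail)] <- pc$x[, seq_len(avail), drop = FALSE]
  if (avail < k)
    warning(sprintf("%s: only %d principal components available, padding to %d",
                    label, avail, k), call. = FALSE)
  list(scores = out, rotation = pc$rotation, center = pc$center)
}

#' 15-feature cohort embedding of spontaneous spiking
#'
#' Builds, for every neuron, the 15-dimensional feature vector used for
#' the 2-D embedding: the first 4 principal components of the cohort ISI
#' histograms, the first 4 of the 500-ms autocorrelograms, the first 4 of
#' the 100-ms autocorrelograms (each PCA fitted on the whole cohort), plus
#' firing rate, CV and burst index. Features are z-scored across the
#' cohort and embedded in 2-D with t-SNE; the result is deterministic
#' given the seed.
#'
#' @param features list of [spike_train_features()] results (>= 10 neurons).
#' @param seed integer seed for the embedding.
#' @param perplexity t-SNE perplexity (default 30; clamped with a warning
#'   when the cohort is small).
#' @return A list with `coords` (n x 2 matrix, rownames = neuron ids),
#'   `features_15` (n x 15 matrix, z-scored), and `pca` (the fitted
#'   loadings, retained for reproducibility).
#' @export
cohort_embedding <- function(features, seed, perplexity = 30) {
  assert_that(length(features) >= 10, "need at least 10 neurons to embed")
  stopifnot(all(vapply(features, inherits, logical(1), "spike_features")))
  ids <- vapply(features, `[[`, character(1), "neuron_id")
  isi <- do.call(rbind, lapply(features, `[[`, "isi_hist"))
  a500 <- do.call(rbind, lapply(features, `[[`, "acg_500"))
  a100 <- do.call(rbind, lapply(features, `[[`, "acg_100"))
  p1 <- pca_scores(isi, 4, "ISI histogram PCA")
  p2 <- pca_scores(a500, 4, "500-ms ACG PCA")
  p3 <- pca_scores(a100, 4, "100-ms ACG PCA")
  F15 <- cbind(p1$scores, p2$scores, p3$scores,
               vapply(features, `[[`, numeric(1), "firing_rate_hz"),
               vapply(features, `[[`, numeric(1), "cv"),
               vapply(features, `[[`, numeric(1), "burst_index"))
  colnames(F15) <- c(paste0("isi_pc", 1:4), paste0("acg500_pc", 1:4),
                     paste0("acg100_pc", 1:4), "firing_rate", "cv",
                     "burst_index")
  sds <- apply(F15, 2, stats::sd)
  Z <- sweep(F15, 2, colMeans(F15))
  Z <- sweep(Z, 2, ifelse(sds > 0, sds, 1), "/")
  coords <- tsne_exact(Z, seed = seed, perplexity = perplexity)
  rownames(coords) <- rownames(Z) <- ids
  list(coords = coords, features_15 = Z,
       pca = list(isi = p1[c("rotation", "center")],
                  acg_500 = p2[c("rotation", "center")],
                  acg_100 = p3[c("rotation", "center")]))
}

#' Foot-shock modulation index
#'
#' The bounded rate-change statistic
#' `(FR_stimulus - FR_baseline) / (FR_stimulus + FR_baseline)`, in
#' `[-1, 1]`. When both rates are zero the index is undefined; it is
#' returned as 0 with attribute `degenerate = TRUE` so cohort tables stay
#' total.
#'
#' @param fr_stimulus,fr_baseline nonnegative firing rates, Hz.
#' @return The modulation index (attribute `degenerate` flags the 0/0
#'   case).
#' @examples
#' fs_modulation_index(3, 1)  # 0.5
#' @export
fs_modulation_index <- function(fr_stimulus, fr_baseline) {
  assert_that(is_scalar_number(fr_stimulus) && is_scalar_number(fr_baseline),
              "rates must be single numbers")
  assert_that(fr_stimulus >= 0 && fr_baseline >= 0, "rates must be nonnegative")
  if (fr_stimulus + fr_baseline == 0)
    return(structure(0, degenerate = TRUE))
  (fr_stimulus - fr_baseline) / (fr_stimulus + fr_baseline)
}

#' Classify a neuron's foot-shock response
#'
#' Compares per-trial spike counts in the 1-s pre-onset baseline window
#' against the 1-s post-onset stimulus window with a Wilcoxon rank-sum
#' test (the matched-pairs signed-rank variant is available behind
#' `paired = TRUE`). Neurons with `p <= alpha` are FS-excited when the
#' stimulus rate exceeds baseline and FS-inhibited when it is lower;
#' otherwise non-modulated. Only neurons with more than 20 foot-shock
#' trials are accepted (fewer raises an exclusion error).
#'
#' @param rec a [spike_train_recording()] with `n_fs_trials > 20`.
#' @param cfg an [analysis_config()] (supplies `alpha`).
#' @param paired use the signed-rank test instead of the rank-sum test.
#' @return An object of class `fs_response`: baseline and stimulus rates,
#'   per-trial counts, p-value, class and modulation index.
#' @export
classify_fs_response <- function(rec, cfg = analysis_config(), paired = FALSE) {
  stopifnot(inherits(rec, "spike_train"))
  if (rec$n_fs_trials <= 20)
    stop_pavcond("neuron %s excluded: %d foot-shock trials (need > 20)",
                 rec$neuron_id, rec$n_fs_trials)
  st <- rec$spike_times_s
  base <- vapply(rec$fs_event_times_s, function(on)
    sum(st >= on - 1 & st < on), numeric(1))
  stim <- vapply(rec$fs_event_times_s, function(on)
    sum(st >= on & st < on + 1), numeric(1))
  fr_b <- mean(base); fr_s <- mean(stim)
  if (all(stim == base)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(stim, base, paired = paired, exact = FALSE)$p.value)
  }
  klass <- "non_modulated"
  if (!is.na(p) && p <= cfg$alpha) {
    if (fr_s > fr_b) klass <- "FS_excited"
    else if (fr_s < fr_b) klass <- "FS_inhibited"
  }
  mi <- fs_modulation_index(fr_s, fr_b)
  structure(list(neuron_id = rec$neuron_id,
                 fr_baseline_hz = fr_b, fr_stimulus_hz = fr_s,
                 per_trial_counts = cbind(baseline = base, stimulus = stim),
                 p_value = p, klass = klass,
                 modulation_index = as.numeric(mi),
                 degenerate = isTRUE(attr(mi, "degenerate"))),
            class = "fs_response")
}

#' @export
print.fs_response <- function(x, ...) {
  cat(sprintf("%s: %s (FRb %.2f Hz, FRs %.2f Hz, mod %.3f, p = %.3g)\n",
              x$neuron_id, x$klass, x$fr_baseline_hz, x$fr_stimulus_hz,
              x$modulation_index, x$p_value))
  invisible(x)
}

#' Correlation between spontaneous rate and foot-shock modulation
#'
#' Pearson correlation (with two-sided p) between per-neuron spontaneous
#' firing rates and foot-shock modulation indices; the population-level
#' statistic relating baseline excitability to punishment modulation.
#'
#' @param firing_rate_hz numeric vector of spontaneous rates.
#' @param modulation_index numeric vector of modulation indices (same
#'   length, >= 3 neurons).
#' @return A list with `r`, `p_value`, `n`.
#' @export
rate_modulation_correlation <- function(firing_rate_hz, modulation_index) {
  assert_that(length(firing_rate_hz) == length(modulation_index),
              "input vectors differ in length")
  ok <- is.finite(firing_rate_hz) & is.finite(modulation_index)
  assert_that(sum(ok) >= 3, "need at least 3 neurons with defined modulation")
  x <- firing_rate_hz[ok]; y <- modulation_index[ok]
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
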