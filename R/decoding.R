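# Per-neuron binary decoding of trial-wise eyeblink from cue-evoked
# activity, with repeated stratified splits, an RBF support vector
# classifier and a shuffle null.

#' Decoder configuration
#'
#' @param low_pct,high_pct percentile band: trials with CR below the
#'   `low_pct` percentile form one class, above the `high_pct` percentile
#'   the other; the band in between is excluded (defaults 40 / 60).
#' @param n_repeats number of repeated stratified train/test splits
#'   (default 100).
#' @param test_fraction held-out fraction per class per split (default 0.2).
#' @param c_grid candidate soft-margin penalties (default
#'   `c(0.1, 1, 10, 100)`).
#' @param gamma_grid candidate RBF kernel widths; `NA` means the scaled
#'   default `1 / (n_features * var(train))` (default
#'   `c(NA, 0.01, 0.1, 1)`).
#' @param seed integer seed; splits, grid selection and the shuffle are
#'   deterministic given it.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(low_pct = 40, high_pct = 60, n_repeats = 100,
                           test_fraction = 0.2,
                           c_grid = c(0.1, 1, 10, 100),
                           gamma_grid = c(NA, 0.01, 0.1, 1),
                           seed = 1L) {
  assert_that(low_pct > 0 && low_pct < high_pct && high_pct < 100,
              "need 0 < low_pct < high_pct < 100")
  assert_that(n_repeats >= 1, "n_repeats must be >= 1")
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  structure(list(low_pct = low_pct, high_pct = high_pct,
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 seed = as.integer(seed)),
            class = "decoder_config")
}

#' Label trials by eyeblink strength
#'
#' Splits a session's trials into strong-blink and weak-blink classes by
#' the session-wise percentiles of the conditioned-response amplitude
#' (linear-interpolation quantiles). CR below the lower percentile (eye
#' more closed, strong blink) is `"high_blink"`, above the upper
#' percentile `"low_blink"`, and the dead band in between is
#' `"excluded"`. Labels depend on CR ranks only, so any strictly monotone
#' transform of CR leaves them unchanged.
#'
#' @param cr_per_trial per-trial CR amplitudes (percent), >= 10 trials.
#' @param cfg a [decoder_config()].
#' @return Character vector of labels (`"high_blink"`, `"low_blink"`,
#'   `"excluded"`).
#' @export
make_blink_labels <- function(cr_per_trial, cfg = decoder_config()) {
  assert_that(length(cr_per_trial) >= 10, "need at least 10 trials to label")
  q <- stats::quantile(cr_per_trial, c(cfg$low_pct, cfg$high_pct) / 100,
                       type = 7, names = FALSE)
  lab <- rep("excluded", length(cr_per_trial))
  lab[cr_per_trial < q[1]] <- "high_blink"
  lab[cr_per_trial > q[2]] <- "low_blink"
  if (!any(lab == "high_blink") || !any(lab == "low_blink"))
    stop_pavcond("labeling failed: a blink class is empty (percentiles %g and %g coincide or no trial clears them)",
                 q[1], q[2])
  lab
}

# Stratified index sample: `fraction` of each class (at least 1), seeded by
# the caller's RNG state.
stratified_test_idx <- function(labels, fraction) {
  unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, max(1, round(fraction * length(idx))))
  }))
}

svm_accuracy <- function(x_tr, y_tr, x_te, y_te, cost, gamma) {
  fit <- e1071::svm(x = matrix(x_tr, ncol = 1), y = factor(y_tr),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  pred <- stats::predict(fit, matrix(x_te, ncol = 1))
  mean(as.character(pred) == y_te)
}

#' Decode eyeblink class from one neuron's cue-window activity
#'
#' For each of `n_repeats` stratified random train/test splits, the
#' feature (per-trial cue-window AUC, standardized on the training split
#' only) is fed to an RBF-kernel support vector classifier; the penalty
#' and kernel width are grid-searched on an inner stratified holdout of
#' the training split, the selected model is refit on the full training
#' split and scored on the test split. The reported accuracy is the mean
#' held-out accuracy over repeats. Deterministic given `cfg$seed`.
#'
#' @param auc_per_trial per-trial cue-window AUC values.
#' @param labels labels from [make_blink_labels()] (same length;
#'   `"excluded"` trials are dropped).
#' @param cfg a [decoder_config()].
#' @return An object of class `decoding_result`: `accuracy`,
#'   `n_trials_used`, `labels_dropped`, `per_repeat` accuracies.
#' @export
decode_single_neuron <- function(auc_per_trial, labels,
                                 cfg = decoder_config()) {
  assert_that(length(auc_per_trial) == length(labels),
              "activity and labels differ in length")
  use <- labels != "excluded"
  x <- auc_per_trial[use]; y <- labels[use]
  tab <- table(y)
  assert_that(length(tab) == 2 && all(tab >= 4),
              "need >= 4 trials per blink class (have: %s)",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  acc <- with_seed(child_seed(cfg$seed, 1L), {
    vapply(seq_len(cfg$n_repeats), function(rep_i) {
      te <- stratified_test_idx(y, cfg$test_fraction)
      tr <- setdiff(seq_along(y), te)
      mu <- mean(x[tr]); sdv <- stats::sd(x[tr]); if (!(sdv > 0)) sdv <- 1
      xs <- (x - mu) / sdv
      # inner stratified holdout of the training split for grid selection
      val <- tr[stratified_test_idx(y[tr], 0.25)]
      fit_tr <- setdiff(tr, val)
      gam_default <- {
        v <- stats::var(xs[tr]); if (is.finite(v) && v > 0) 1 / v else 1
      }
      grid <- expand.grid(cost = cfg$c_grid, gamma = cfg$gamma_grid)
      grid$gamma[is.na(grid$gamma)] <- gam_default
      val_acc <- mapply(function(cost, gamma)
        svm_accuracy(xs[fit_tr], y[fit_tr], xs[val], y[val], cost, gamma),
        grid$cost, grid$gamma)
      best <- grid[which.max(val_acc), ]  # ties: first (smallest C, then gamma)
      svm_accuracy(xs[tr], y[tr], xs[te], y[te], best$cost, best$gamma)
    }, numeric(1))
  })
  structure(list(accuracy = mean(acc), per_repeat = acc,
                 n_trials_used = length(x),
                 labels_dropped = sum(!use)),
            class = "decoding_result")
}

#' Shuffle null for a decoded neuron
#'
#' Permutes the blink labels of the included trials once, uniformly at
#' random (seeded), then applies the identical decoding procedure — same
#' splits, same grids — so the comparison with the unshuffled run is
#' paired and an identity permutation reproduces it exactly. The resulting
#' accuracy is the chance-level reference for that neuron.
#'
#' @inheritParams decode_single_neuron
#' @param permutation optional explicit permutation of the included trials
#'   (for forced-identity checks); default draws one from the seed.
#' @return A `decoding_result` for the shuffled labels.
#' @export
shuffle_null <- function(auc_per_trial, labels, cfg = decoder_config(),
                         permutation = NULL) {
  use <- which(labels != "excluded")
  perm <- permutation %||%
    with_seed(child_seed(cfg$seed, 999983L), sample(length(use)))
  assert_that(length(perm) == length(use), "permutation length mismatch")
  shuffled <- labels
  shuffled[use] <- labels[use][perm]
  decode_single_neuron(auc_per_trial, shuffled, cfg)
}

#' Population test of decoding accuracy against the shuffle null
#'
#' Unpaired t-test of per-neuron accuracy versus per-neuron shuffle
#' accuracy.
#'
#' @param accuracy,shuffle_accuracy per-neuron accuracy vectors.
#' @return A list with `t`, `df`, `p_value`, `mean_accuracy`,
#'   `mean_shuffle`.
#' @export
decoding_significance <- function(accuracy, shuffle_accuracy) {
  assert_that(length(accuracy) >= 2 && length(shuffle_accuracy) >= 2,
              "need at least 2 neurons per group")
  if (stats::sd(accuracy) == 0 && stats::sd(shuffle_accuracy) == 0) {
    if (isTRUE(all.equal(mean(accuracy), mean(shuffle_accuracy))))
      stop_pavcond("degenerate test: both accuracy groups are constant and equal")
    stop_pavcond("degenerate test: zero variance in both accuracy groups")
  }
  tt <- stats::t.test(accuracy, shuffle_accuracy)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_accuracy = mean(accuracy),
       mean_shuffle = mean(shuffle_accuracy))
}
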