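# dF/F0, window AUC, response classification, plasticity and RAF.

test_that("dF/F0 follows the ratio formula and is gain-invariant", {
  w <- trace_window(5, 5, 15)
  tt <- window_times(w)
  raw <- matrix(100, 2, w$n_samples)
  raw[1, tt >= 0 & tt < 1] <- 150
  ts <- neuron_trace_set("n", "s", "conditioning", w, c("CSplus", "CSplus"), raw)
  d <- compute_dff(ts)
  expect_equal(unname(d$dff_pct[1, tt >= 0 & tt < 1]),
               rep(50, sum(tt >= 0 & tt < 1)))
  expect_equal(unname(d$dff_pct[2, ]), rep(0, w$n_samples))
  ts_k <- neuron_trace_set("n", "s", "conditioning", w, c("CSplus", "CSplus"),
                           3.7 * raw)
  expect_equal(compute_dff(ts_k)$dff_pct, d$dff_pct)
  # non-positive F0 flags the trial invalid
  raw_bad <- raw; raw_bad[2, ] <- 0
  ts_b <- neuron_trace_set("n", "s", "conditioning", w, c("CSplus", "CSplus"), raw_bad)
  expect_warning(db <- compute_dff(ts_b), "non-positive F0")
  expect_true(all(is.na(db$dff_pct[2, ])))
})

test_that("window AUC is a trapezoidal integral with linearity", {
  w <- trace_window(5, 5, 15)
  const10 <- rep(10, w$n_samples)
  expect_equal(trial_window_auc(const10, c(0, 1.5), w), 15)
  expect_equal(trial_window_auc(rep(0, w$n_samples), c(0, 1.5), w), 0)
  set.seed(2)
  x <- rnorm(w$n_samples)
  expect_equal(trial_window_auc(2 * x, c(-1.5, 0), w),
               2 * trial_window_auc(x, c(-1.5, 0), w))
  expect_error(trial_window_auc(const10, c(9, 11), w), "outside trace")
})

test_that("noiseless responses classify deterministically in the planted direction", {
  w <- trace_window(5, 5, 15)
  tt <- window_times(w)
  kern <- ifelse(tt < 0, 0, (1 - exp(-tt / 0.05)) * exp(-tt / 0.5))
  kern <- kern / max(kern)
  sig <- matrix(0, 10, w$n_samples)
  for (i in 1:10) sig[i, ] <- -20 * kern   # inhibited, amp -20 %
  ts <- trace_set_from_signal(sig, rep("CSplus", 10))
  r <- classify_cue_response(ts)
  expect_equal(r$klass, "inhibited")
  expect_lte(r$p_value, 0.05)
  # excited with noise
  set.seed(3)
  sig2 <- matrix(rnorm(30 * length(kern), 0, 5), 30, byrow = FALSE,
                 dimnames = NULL) + matrix(20 * kern, 30, length(kern), byrow = TRUE)
  ts2 <- trace_set_from_signal(sig2, rep("CSplus", 30))
  expect_equal(classify_cue_response(ts2)$klass, "excited")
  expect_error(classify_cue_response(trace_set_from_signal(sig[1:3, ], rep("CSplus", 3))),
               "excluded")
})

test_that("airpuff-epoch classification uses the duration-matched comparison", {
  w <- trace_window(5, 5, 15)
  tt <- window_times(w)
  sig <- matrix(0, 8, w$n_samples)
  sig[, tt >= 1.5 & tt < 2.0] <- 25    # response only in the airpuff epoch
  ts <- trace_set_from_signal(sig, rep("CSplus", 8))
  r_us <- classify_cue_response(ts, response = "us")
  expect_equal(r_us$klass, "excited")
  r_ant <- classify_cue_response(ts, response = "anticipatory")
  expect_equal(r_ant$klass, "nonresponsive")
})

test_that("plasticity contingency reproduces the hand-computed statistic", {
  # table [[10,10,10],[5,10,15]]: expected cells 7.5/10/12.5 per row,
  # chi2 = 2 * (2.5^2/7.5 + 0 + 2.5^2/12.5) = 8/3
  pt <- plasticity_contingency(c(inhibited = 10, nonresponsive = 10, excited = 10),
                               c(inhibited = 5, nonresponsive = 10, excited = 15))
  expect_equal(pt$chi2, 8 / 3, tolerance = 1e-9)
  expect_equal(pt$df, 2)
  # identical rows and proportional rows both give chi2 = 0, p = 1
  id <- plasticity_contingency(c(inhibited = 3, nonresponsive = 5, excited = 7),
                               c(inhibited = 3, nonresponsive = 5, excited = 7))
  expect_equal(id$chi2, 0); expect_equal(id$p_value, 1)
  pr <- plasticity_contingency(c(inhibited = 3, nonresponsive = 5, excited = 7),
                               c(inhibited = 6, nonresponsive = 10, excited = 14))
  expect_equal(pr$chi2, 0)
  # a class empty in both phases is dropped with df adjustment
  expect_warning(
    dr <- plasticity_contingency(c(inhibited = 0, nonresponsive = 10, excited = 10),
                                 c(inhibited = 0, nonresponsive = 5, excited = 15)),
    "dropping class")
  expect_equal(dr$df, 1)
})

test_that("plasticity test rejects on the default plastic cohort", {
  s <- fixture_schedules()
  ca <- generate_calcium_cohort(calcium_cohort_params(n_neurons = 100, seed = 51),
                                s$hab, s$cond)
  cl <- vapply(ca$neurons, function(nn)
    c(classify_cue_response(nn$hab)$klass, classify_cue_response(nn$cond)$klass),
    character(2))
  pt <- plasticity_contingency(cl[1, ], cl[2, ])
  expect_lt(pt$p_value, 0.05)
  # more responders in conditioning than habituation
  expect_gt(sum(cl[2, ] != "nonresponsive"), sum(cl[1, ] != "nonresponsive"))
})

test_that("relative fluorescence follows the normalized difference", {
  expect_equal(relative_fluorescence(300, 100)$raf, 0.5)
  expect_equal(relative_fluorescence(42, 42)$raf, 0)
  expect_equal(relative_fluorescence(0, 7)$raf, -1)
  expect_error(relative_fluorescence(0, 0), "both zero")
})
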