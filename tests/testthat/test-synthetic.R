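# Generators: planted structure, determinism, closed-form checks.

test_that("task schedules have the protocol's trial mix and are deterministic", {
  s <- fixture_schedules()$hab
  expect_equal(as.numeric(table(s$trials$cue)[c("CSplus", "CSminus", "US_unpredicted")]),
               c(30, 30, 5))
  expect_false(any(s$trials$paired_us))
  sc <- fixture_schedules()$cond
  expect_equal(sum(sc$trials$cue == "CSplus"), 30)
  expect_equal(sum(sc$trials$cue == "CSminus"), 30)
  expect_true(all(sc$trials$paired_us[sc$trials$cue == "CSplus"]))
  expect_identical(generate_task_schedule("habituation", 5),
                   generate_task_schedule("habituation", 5))
  # ITIs inside the protocol bounds
  gaps <- diff(s$trials$onset_s)
  lens <- ifelse(s$trials$cue == "US_unpredicted", 0.5, 2)[-nrow(s$trials)]
  expect_true(all(gaps - lens >= 30 & gaps - lens <= 45))
})

test_that("spike cohorts plant the rate/modulation coupling", {
  co <- generate_spike_cohort(spike_cohort_params(n_neurons = 200, seed = 3,
                                                  duration_s = 2, n_fs_trials = 1))
  r <- cor(log(co$truth$baseline_rate_hz), co$truth$true_mod)
  expect_lt(abs(r - (-0.5)), 0.15)
  # class proportions land at the planted fractions
  expect_equal(sum(co$truth$class == "FS_excited"), 136, tolerance = 0)
  # modulation sign consistent with class
  expect_true(all(co$truth$true_mod[co$truth$class == "FS_excited"] > 0))
  expect_true(all(co$truth$true_mod[co$truth$class == "FS_inhibited"] < 0))
  expect_true(all(co$truth$true_mod[co$truth$class == "non_modulated"] == 0))
  expect_error(spike_cohort_params(frac_excited = 0, frac_inhibited = 0,
                                   frac_nonmod = 1, coupling_rho = -0.5),
               "infeasible coupling")
})

test_that("a null spike cohort plants zero modulation and generators are pure", {
  p <- spike_cohort_params(n_neurons = 5, effect_ratio = 1, duration_s = 30,
                           n_fs_trials = 21, seed = 7)
  co <- generate_spike_cohort(p)
  expect_true(all(co$truth$true_mod == 0))
  expect_true(all(co$truth$effect_ratio == 1))
  co2 <- generate_spike_cohort(p)
  expect_identical(lapply(co$recordings, `[[`, "spike_times_s"),
                   lapply(co2$recordings, `[[`, "spike_times_s"))
})

test_that("Poisson trains reproduce the analytic burst index", {
  # for exponential ISIs at rate r, P(ISI < 25 ms) = 1 - exp(-0.025 r)
  co <- generate_spike_cohort(spike_cohort_params(
    n_neurons = 20, rate_median_hz = 6, rate_sigma = 0, burst_prob = 0,
    effect_ratio = 1, coupling_rho = 0, duration_s = 600, n_fs_trials = 21,
    seed = 3))
  bi <- vapply(co$recordings, function(r) spike_train_features(r)$burst_index,
               numeric(1))
  expect_lt(abs(mean(bi) - (1 - exp(-6 * 0.025))), 0.01)
  # with the simulator's 1-ms refractory period the exact value is
  # P(ISI < 25 ms | ISI > 1 ms) = 1 - exp(-rate * 0.024)
  expect_lt(abs(mean(bi) - (1 - exp(-6 * 0.024))), 0.004)
})

test_that("noiseless calcium transients peak at the planted amplitude", {
  s <- fixture_schedules()
  ca <- generate_calcium_cohort(
    calcium_cohort_params(n_neurons = 3, class_probs = c(1, 0, 0),
                          amp_cond = 20, noise_sd = 0, amp_latent_sd = 0,
                          amp_jitter = 0, seed = 4), s$hab, s$cond)
  expect_true(all(ca$truth$neurons$class == "excited"))
  nn <- compute_dff(ca$neurons[[1]]$cond)
  plus <- nn$cue_per_trial == "CSplus"
  # peak over the cue window (the paired airpuff adds its own transient
  # later in the trial)
  tt <- window_times(nn$window)
  cuew <- tt >= 0 & tt < 1.5
  peaks <- apply(nn$dff_pct[plus, cuew, drop = FALSE], 1, max)
  expect_equal(unname(peaks), rep(20, sum(plus)), tolerance = 1e-9)
  # CS- trials carry no planted response
  expect_true(all(abs(nn$dff_pct[!plus, ]) < 1e-9))
  expect_error(
    generate_calcium_cohort(
      calcium_cohort_params(decay_s = 5), s$hab, s$cond),
    "kernel longer")
})

test_that("non-learner mice have zero expected discrimination; depth sets CR exactly", {
  s <- fixture_schedules()
  be0 <- generate_behavior(behavior_params(n_mice = 3, learner = FALSE,
                                           blink_noise_sd = 0, seed = 5),
                           s$hab, s$cond)
  sc0 <- vapply(be0$mice, function(m) discrimination_score(m$cond), numeric(1))
  expect_equal(sc0, rep(0, 3), tolerance = 1e-9)
  # depth 0.3, no noise: CS+ CR = 70 %, discrimination = 30
  be <- generate_behavior(behavior_params(n_mice = 1, cr_depth_cond = 0.3,
                                          blink_noise_sd = 0, seed = 6),
                          s$hab, s$cond)
  bs <- behavior_summary(be$mice[[1]]$cond)
  expect_equal(bs$cr_mean_csplus, 70, tolerance = 1e-9)
  expect_equal(bs$cr_mean_csminus, 100, tolerance = 1e-9)
  expect_equal(bs$discrimination_score, 30, tolerance = 1e-9)
})

test_that("full coupling makes CR rank order follow the neural latent", {
  s <- fixture_schedules()
  ca <- generate_calcium_cohort(calcium_cohort_params(n_neurons = 2, seed = 8),
                                s$hab, s$cond)
  be <- generate_behavior(behavior_params(n_mice = 1, neuron_coupling = 1,
                                          blink_noise_sd = 0, seed = 9),
                          s$hab, s$cond, calcium_truth = ca$truth)
  bs <- behavior_summary(be$mice[[1]]$cond)
  plus <- bs$cue_per_trial == "CSplus"
  lat <- ca$truth$trials$amp_latent[ca$truth$trials$phase == "conditioning"][plus]
  cr <- bs$cr_amplitude_per_trial[plus]
  # stronger shared activity -> deeper blink -> lower CR, rank for rank
  expect_equal(order(cr), order(-lat))
  expect_error(generate_behavior(behavior_params(neuron_coupling = 0.5),
                                 s$hab, s$cond), "calcium_truth")
})

test_that("photometry counts are Poisson around the planted rate profile and seeded", {
  s <- fixture_schedules()
  p <- photometry_params("potentiating", seed = 10)
  g1 <- generate_photometry(p, s$hab, s$cond)
  g2 <- generate_photometry(p, s$hab, s$cond)
  expect_identical(g1$series$counts, g2$series$counts)
  expect_equal(p$amp_cond[["csplus"]], 2 * p$amp_hab[["csplus"]])
  # far from events the mean count is the base rate
  expect_lt(abs(mean(g1$series$counts[1:2000]) - 50), 0.6)
  st <- photometry_params("stable", seed = 10)
  expect_identical(st$amp_hab, st$amp_cond)
})
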