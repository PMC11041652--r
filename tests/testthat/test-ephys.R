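# Spike-train features, foot-shock classification and the embedding.

test_that("ISI features match hand-computed values", {
  rec <- spike_train_from_isis(c(0.010, 0.030, 0.020, 0.050))
  f <- spike_train_features(rec)
  expect_equal(f$burst_index, 0.5)       # 2 of 4 ISIs below 25 ms
  isis <- c(0.010, 0.030, 0.020, 0.050)
  expect_equal(f$cv, sd(isis) / mean(isis))
  expect_equal(sum(f$isi_hist), 1)
  # 10-ms bins: ISIs fall in bins 1, 3, 2, 5
  expect_equal(which(f$isi_hist > 0), c(1, 2, 3, 5))
})

test_that("a perfectly regular train has zero CV and the exact rate", {
  st <- seq(0.2, 60, by = 0.2)
  rec <- spike_train_recording("reg", st, 60)
  f <- spike_train_features(rec)
  expect_equal(f$cv, 0)
  expect_equal(f$firing_rate_hz, 5)
  expect_equal(f$burst_index, 0)
  expect_error(spike_train_features(spike_train_recording("one", 1, 10)),
               "insufficient")
})

test_that("ISI-based features are invariant under time translation", {
  isis <- c(0.01, 0.2, 0.05, 0.4, 0.02, 0.15)
  f1 <- spike_train_features(spike_train_from_isis(isis, start = 0.5))
  f2 <- spike_train_features(spike_train_from_isis(isis, start = 20.5))
  for (field in c("cv", "burst_index", "isi_hist", "acg_500", "acg_100"))
    expect_equal(f1[[field]], f2[[field]])
})

test_that("foot-shock windows are excised from spontaneous statistics", {
  # 10-Hz regular spiking, one FS at 50 s: the 1-s window holds 10 spikes
  st <- seq(0.1, 100, by = 0.1)
  rec_fs <- spike_train_recording("x", st, 100, fs_event_times_s = 50)
  rec_no <- spike_train_recording("x", st, 100)
  f_fs <- spike_train_features(rec_fs)
  f_no <- spike_train_features(rec_no)
  expect_equal(f_no$firing_rate_hz, 10, tolerance = 1e-3)
  expect_equal(f_fs$firing_rate_hz, 10, tolerance = 1e-3)  # rate unchanged after excision
  expect_lt(sum(lengths(list(f_fs$isi_hist))), Inf)
})

test_that("modulation index follows the exact formula and is antisymmetric", {
  expect_equal(fs_modulation_index(3, 1), 0.5)
  expect_equal(fs_modulation_index(2, 2), 0)
  expect_equal(fs_modulation_index(0, 4), -1)
  for (ab in list(c(1, 3), c(0.2, 7), c(5, 0)))
    expect_equal(fs_modulation_index(ab[1], ab[2]),
                 -fs_modulation_index(ab[2], ab[1]))
  z <- fs_modulation_index(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(fs_modulation_index(-1, 2), "nonnegative")
})

test_that("foot-shock classification recovers planted classes and excludes short runs", {
  co <- generate_spike_cohort(spike_cohort_params(
    n_neurons = 60, effect_ratio = 3, duration_s = 60, seed = 21))
  cls <- vapply(co$recordings, function(r) classify_fs_response(r)$klass, "")
  expect_gte(mean(cls == co$truth$class), 0.9)
  # direction never contradicts the planted sign when significant
  res <- lapply(co$recordings, classify_fs_response)
  for (i in seq_along(res)) {
    if (res[[i]]$klass == "FS_excited") expect_gt(co$truth$true_mod[i], -1e-12)
    if (res[[i]]$klass == "FS_inhibited") expect_lt(co$truth$true_mod[i], 1e-12)
  }
  short <- spike_train_recording("s", seq(0.5, 99.5, 0.5), 110,
                                 fs_event_times_s = seq(100, 105, length.out = 20))
  expect_error(classify_fs_response(short), "excluded")
})

test_that("a silent neuron yields the degenerate zero modulation index", {
  rec <- spike_train_recording("z", c(0.1, 0.2), 200,
                               fs_event_times_s = 50 + 5 * (1:21))
  r <- classify_fs_response(rec)
  expect_equal(r$modulation_index, 0)
  expect_true(r$degenerate)
  expect_equal(r$klass, "non_modulated")
})

test_that("rate/modulation correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rate_modulation_correlation(x, -2 * x + 1)$r, -1)
  expect_error(rate_modulation_correlation(x, rep(0.3, 5)), "zero variance")
  expect_error(rate_modulation_correlation(1:2, 2:1), "at least 3")
})

test_that("cohort embedding is 15-dimensional, deterministic, duplicate-consistent", {
  co <- generate_spike_cohort(spike_cohort_params(
    n_neurons = 12, duration_s = 120, effect_ratio = 1, coupling_rho = 0,
    seed = 22))
  feats <- lapply(co$recordings, spike_train_features)
  feats[[12]] <- feats[[1]]  # duplicated neuron
  expect_warning(emb <- cohort_embedding(feats, seed = 5), "perplexity")
  expect_equal(ncol(emb$features_15), 15L)
  expect_equal(emb$features_15[12, ], emb$features_15[1, ], ignore_attr = TRUE)
  expect_warning(emb2 <- cohort_embedding(feats, seed = 5), "perplexity")
  expect_identical(emb$coords, emb2$coords)
  expect_error(cohort_embedding(feats[1:5], seed = 1), "at least 10")
})

test_that("planted feature clusters separate in the embedding", {
  co1 <- generate_spike_cohort(spike_cohort_params(
    n_neurons = 25, rate_median_hz = 12, rate_sigma = 0.1, gamma_shape = 8,
    burst_prob = 0, effect_ratio = 1, coupling_rho = 0, duration_s = 120,
    seed = 31))
  co2 <- generate_spike_cohort(spike_cohort_params(
    n_neurons = 25, rate_median_hz = 2, rate_sigma = 0.1, gamma_shape = 1,
    burst_prob = 0.4, effect_ratio = 1, coupling_rho = 0, duration_s = 120,
    seed = 32))
  feats <- c(lapply(co1$recordings, spike_train_features),
             lapply(co2$recordings, spike_train_features))
  emb <- suppressWarnings(cohort_embedding(feats, seed = 7, perplexity = 12))
  lab <- rep(1:2, each = 25)
  d <- as.matrix(dist(emb$coords))
  sil <- vapply(seq_len(50), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
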