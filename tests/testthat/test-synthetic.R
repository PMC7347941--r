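test_that("default signal models encode the analyte amplitude and fluctuation structure", {
  mods <- default_signal_models()
  expect_equal(mods$amplitude_mean[mods$class == "DA"], 15)
  expect_equal(mods$amplitude_mean[mods$class == "NE"], 14)
  expect_equal(mods$amplitude_mean[mods$class == "5HT"], 15)
  expect_true(all(mods$amplitude_sd == 7))
  fl <- setNames(mods$fluctuation_scale, mods$class)
  expect_true(fl[["5HT"]] > fl[["DA"]])
  expect_true(fl[["DA"]] > fl[["NE"]])
  expect_equal(sum(mods$weight), 1)
  # log-normal median dwell = exp(meanlog) = 10 ms
  expect_equal(unique(exp(mods$dwell_meanlog)), 0.010)
})

test_that("trace simulation is deterministic and respects degenerate configs", {
  cfg <- sim_config(duration = 1, seed = 7)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$current_pA, b$trace$current_pA)
  expect_identical(a$truth$pulses, b$truth$pulses)

  quiet <- sim_config(duration = 0.5, pulse_rate = 0, artifact_rate = 0,
    baseline_noise_sd = 0, seed = 1)
  sim <- simulate_trace(quiet)
  base <- tunnelling_current(quiet$gap_width_nm, quiet$bias_voltage)
  expect_equal(unique(sim$trace$current_pA), base)
  expect_true(sim$truth$low_event_warning)
  expect_equal(nrow(sim$truth$pulses), 0)
})

test_that("pulse arrivals follow the configured Poisson rate", {
  # rate 2/s over 100 s: mean count over 50 seeds within 3*sqrt(200) of 200
  counts <- vapply(1:50, function(s) {
    cfg <- sim_config(duration = 100, sampling_rate = 1000, pulse_rate = 2,
      artifact_rate = 0, seed = s)
    simulate_trace(cfg)$truth$n_pulse_events
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200))
})

test_that("ground-truth pulse spans never overlap and merges are flagged", {
  for (s in 1:5) {
    sim <- simulate_trace(sim_config(duration = 5, pulse_rate = 8,
      artifact_rate = 0, seed = s))
    tr <- sim$truth$pulses
    expect_true(all(tr$onset_sample[-1] >= tr$offset_sample[-nrow(tr)]))
    expect_true(is.logical(tr$merged))
  }
})

test_that("feature-space generator matches its nominal class models", {
  fs <- simulate_feature_set(n_per_class = 100, seed = 1)
  expect_equal(nrow(fs), 300)
  expect_identical(fs, simulate_feature_set(n_per_class = 100, seed = 1))

  # per-class mean amplitude converges to amplitude_mean (SE bound, n=1000)
  fs_big <- simulate_feature_set(n_per_class = 1000, seed = 2)
  mean_cur <- rowMeans(fs_big[, paste0("I", 1:10)])
  for (cl in nanosig_classes()) {
    mods <- default_signal_models()
    mu <- mods$amplitude_mean[mods$class == cl]
    se <- mods$amplitude_sd[mods$class == cl] / sqrt(1000)
    expect_lt(abs(mean(mean_cur[fs_big$label == cl]) - mu), 4 * se)
  }
})

test_that("generated 5-HT fluctuation factors stochastically dominate NE", {
  fs <- simulate_feature_set(n_per_class = 500, seed = 3)
  w <- wilcox.test(
    fs$fluctuation_factor[fs$label == "5HT"],
    fs$fluctuation_factor[fs$label == "NE"],
    alternative = "greater"
  )
  expect_lt(w$p.value, 0.01)
})

test_that("overlap_control interpolates towards separable classes", {
  sep <- simulate_feature_set(n_per_class = 50, overlap_control = 0, seed = 4)
  mean_cur <- rowMeans(sep[, paste0("I", 1:10)])
  ranges <- tapply(mean_cur, sep$label, range)
  # class amplitude supports must be disjoint at overlap_control = 0
  sorted <- ranges[order(vapply(ranges, min, numeric(1)))]
  for (i in seq_len(length(sorted) - 1)) {
    expect_lt(sorted[[i]][2], sorted[[i + 1]][1])
  }
})

test_that("mixing weights must sum to one", {
  mods <- default_signal_models()
  mods$weight <- c(0.5, 0.2, 0.2)
  expect_error(sim_config(models = mods), class = "nanosig_config_error")
})
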