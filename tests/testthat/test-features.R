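test_that("ten-region averages reproduce hand-computed values", {
  # constant pulse: every region mean equals the amplitude
  const <- extract_features(manual_pulse(rep(10, 100)), label = "DA")
  expect_equal(as.numeric(const[1, paste0("I", 1:10)]), rep(10, 10))
  expect_equal(const$fluctuation_factor, 0)

  # 20-sample ramp 1..20 pA: two samples per region
  ramp <- extract_features(manual_pulse(1:20), label = "DA")
  expect_equal(as.numeric(ramp[1, paste0("I", 1:10)]),
    c(1.5, 3.5, 5.5, 7.5, 9.5, 11.5, 13.5, 15.5, 17.5, 19.5))

  # baseline subtraction
  shifted <- extract_features(manual_pulse(1:20 + 100, baseline = 100),
    label = "DA")
  expect_equal(as.numeric(shifted[1, paste0("I", 1:10)]),
    as.numeric(ramp[1, paste0("I", 1:10)]))

  expect_error(extract_features(manual_pulse(1:9)),
    class = "nanosig_feature_error")
})

test_that("remainder samples are assigned one each to the leading regions", {
  # 23 samples -> region sizes (3,3,3,2,2,2,2,2,2,2)
  x <- rep(seq_len(10), times = c(3, 3, 3, rep(2, 7)))
  f <- extract_features(manual_pulse(as.numeric(x)), label = "DA")
  expect_equal(as.numeric(f[1, paste0("I", 1:10)]), as.numeric(1:10))
  # conservation: every sample in exactly one region, any length
  for (n in c(10, 11, 57, 100, 103)) {
    sizes <- tabulate(nanosig:::region_assignment(n, 10L), 10)
    expect_equal(sum(sizes), n)
    expect_true(max(sizes) - min(sizes) <= 1)
    expect_true(all(diff(sizes) <= 0)) # extras lead
  }
})

test_that("feature extraction is linear and the fluctuation factor scale-invariant", {
  set.seed(4)
  s <- abs(rnorm(57, 10, 3))
  f1 <- extract_features(manual_pulse(s), label = "DA")
  f2 <- extract_features(manual_pulse(3 * s), label = "DA")
  expect_equal(as.numeric(f2[1, paste0("I", 1:10)]),
    3 * as.numeric(f1[1, paste0("I", 1:10)]))
  expect_equal(f2$fluctuation_factor, f1$fluctuation_factor)
})

test_that("fluctuation factor matches the published example vector", {
  I <- c(22.1, 20.8, 27.6, 23.7, 23.5, 21.4, 19.5, 28.8, 26.8, 31.3)
  expect_equal(mean(I), 24.55)
  expect_equal(fluctuation_factor(I), (31.3 - 24.55) / 24.55)
  expect_equal(fluctuation_factor(I), 0.275, tolerance = 0.002)
  expect_equal(fluctuation_factor(rep(7, 10)), 0)
  expect_error(fluctuation_factor(c(-5, rep(0, 9))),
    class = "nanosig_domain_error")
})

test_that("current histograms bin per-signal means anchored at zero", {
  h <- current_histogram(c(15.4), bin_size = 1)
  expect_equal(h$bin_left, 15)
  expect_equal(h$bin_right, 16)
  expect_equal(h$count, 1L)

  expect_equal(nrow(current_histogram(numeric())), 0)

  da <- single_class_features("DA", 5000, seed = 6)
  h2 <- current_histogram(da, bin_size = 1)
  centers <- (h2$bin_left + h2$bin_right) / 2
  expect_equal(sum(centers * h2$count) / sum(h2$count), 15, tolerance = 0.3)
  expect_equal(sum(h2$count), 5000)
})

test_that("kernel density estimates are normalized and match the normal law", {
  set.seed(8)
  d <- kde_density(rnorm(1e4))
  at0 <- d$density[which.min(abs(d$x))]
  expect_equal(at0, dnorm(0), tolerance = 0.05 * dnorm(0))
  integral <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)

  expect_error(kde_density(rep(0, 50)), class = "nanosig_domain_error")
  expect_error(kde_density(1), class = "nanosig_domain_error")
})

test_that("dwell-time summaries recover medians and omit empty classes", {
  one <- dwell_time_summary(manual_pulse(rep(5, 100)) |>
    extract_features(label = "DA"))
  expect_equal(one$summary$median, 0.01)

  set.seed(9)
  tab <- tibble::tibble(dwell_time_s = rlnorm(500, log(0.01), 0.5),
    label = "DA")
  smry <- dwell_time_summary(tab)$summary
  expect_equal(smry$median, 0.01, tolerance = 0.1)
  expect_false("NE" %in% smry$label)
  expect_error(dwell_time_summary(tab[0, ]), class = "nanosig_domain_error")
})

test_that("detected fluctuation-factor ordering survives trace-level extraction", {
  med <- vapply(nanosig_classes(), function(cl) {
    mods <- default_signal_models()
    cfg <- sim_config(duration = 10, pulse_rate = 4, artifact_rate = 0,
      models = dplyr::mutate(mods[mods$class == cl, ], weight = 1),
      seed = 17)
    sim <- simulate_trace(cfg)
    f <- extract_features(detect_pulses(sim$trace), label = cl)
    median(f$fluctuation_factor)
  }, numeric(1))
  expect_gt(med[["5HT"]], med[["DA"]])
  expect_gt(med[["DA"]], med[["NE"]])
})
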