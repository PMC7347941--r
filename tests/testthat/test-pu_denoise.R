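test_that("separable positives score near one and artifacts near zero", {
  # disjoint feature supports: signal amplitudes ~15 pA, artifacts ~150 pA
  pure <- simulate_feature_set(n_per_class = 100, seed = 1)
  unl <- noise_feature_set(300, seed = 3)
  m <- fit_pu(pure, unl, seed = 5)
  fresh_pos <- simulate_feature_set(n_per_class = 50, seed = 7)
  expect_gt(mean(pu_scores(m, fresh_pos)), 0.99)
  fresh_noise <- noise_feature_set(100, seed = 8)
  noise_scores <- pu_scores(m, fresh_noise)
  expect_gte(mean(noise_scores < m$decision_threshold), 0.95)
  expect_lt(median(noise_scores), 0.25)
})

test_that("PU calibration recovers the positive fraction of a mixed set", {
  pure <- simulate_feature_set(n_per_class = 200, seed = 1)
  ests <- vapply(1:5, function(s) {
    unl <- rbind(
      dplyr::mutate(simulate_feature_set(n_per_class = 167, seed = 100 + s),
        label = "UNLABELED"),
      noise_feature_set(499, seed = 200 + s)
    )
    estimate_positive_fraction(fit_pu(pure, unl, seed = s), unl)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 501 / 1000), 0.05)
})

test_that("PU fitting is deterministic and rejects degenerate inputs", {
  pure <- simulate_feature_set(n_per_class = 50, seed = 1)
  unl <- noise_feature_set(60, seed = 2)
  m1 <- fit_pu(pure, unl, seed = 3)
  m2 <- fit_pu(pure, unl, seed = 3)
  probe <- simulate_feature_set(n_per_class = 20, seed = 4)
  expect_identical(pu_scores(m1, probe), pu_scores(m2, probe))

  expect_error(fit_pu(pure, pure, seed = 1),
    class = "nanosig_calibration_error")
  expect_error(fit_pu(pure[1:5, ], unl, seed = 1),
    class = "nanosig_config_error")
})

test_that("score_and_filter partitions exhaustively and is idempotent", {
  pure <- simulate_feature_set(n_per_class = 100, seed = 1)
  unl <- rbind(
    dplyr::mutate(simulate_feature_set(n_per_class = 50, seed = 2),
      label = "UNLABELED"),
    noise_feature_set(100, seed = 3)
  )
  m <- fit_pu(pure, unl, seed = 4)

  empty <- unl[0, ]
  out0 <- score_and_filter(m, empty)
  expect_equal(nrow(out0$kept), 0)
  expect_equal(nrow(out0$removed), 0)

  out <- score_and_filter(m, unl)
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(unl))
  expect_length(intersect(out$kept$signal_id, out$removed$signal_id), 0)

  again <- score_and_filter(m, dplyr::select(out$kept, -pu_score))
  expect_equal(nrow(again$removed), 0)
  expect_equal(nrow(again$kept), nrow(out$kept))
})

test_that("separable artifacts are removed with few signals lost", {
  pure <- simulate_feature_set(n_per_class = 200, seed = 1)
  lost <- removed <- numeric(0)
  for (s in 1:5) {
    sig <- dplyr::mutate(simulate_feature_set(n_per_class = 133,
      seed = 300 + s), label = "UNLABELED")
    art <- noise_feature_set(100, seed = 400 + s)
    cand <- dplyr::mutate(rbind(sig, art),
      signal_id = sprintf("c%04d", seq_len(nrow(sig) + nrow(art))))
    m <- fit_pu(pure, cand, seed = s)
    sc <- pu_scores(m, cand)
    lost <- c(lost, mean(sc[seq_len(nrow(sig))] < 0.5))
    removed <- c(removed, mean(sc[-seq_len(nrow(sig))] < 0.5))
  }
  expect_gte(mean(removed), 0.95)
  expect_lte(mean(lost), 0.05)
})

test_that("two-round denoising keeps clean samples and conserves rows", {
  pure <- simulate_feature_set(n_per_class = 150, seed = 1)
  blank <- noise_feature_set(120, seed = 2)
  clean_sample <- dplyr::mutate(
    simulate_feature_set(n_per_class = 100, seed = 3),
    label = "UNLABELED", signal_id = sprintf("s%04d", 1:300)
  )
  den <- two_round_denoise(pure, blank, clean_sample, seed = 4)
  expect_gte(nrow(den$survivors) / nrow(clean_sample), 0.9)

  ann <- tidy(den)
  expect_setequal(ann$signal_id, clean_sample$signal_id)
  expect_equal(sum(is.na(ann$removed_round)), nrow(den$survivors))
  g <- glance(den)
  expect_equal(g$removed_round1 + g$removed_round2 + g$kept, g$n_sample)
})

test_that("two-round denoising separates the three noise populations with provenance", {
  pure <- simulate_feature_set(n_per_class = 200, seed = 1)
  blank <- noise_feature_set(150, seed = 2)
  sample_tbl <- dplyr::bind_rows(
    dplyr::mutate(simulate_feature_set(n_per_class = 150, seed = 3),
      label = "UNLABELED"),
    noise_feature_set(80, seed = 4),
    contaminant_feature_set(80, seed = 5)
  )
  pop <- rep(c("signal", "artifact", "contaminant"), c(450, 80, 80))
  sample_tbl <- dplyr::mutate(sample_tbl, label = "UNLABELED",
    signal_id = sprintf("s%05d", seq_len(nrow(sample_tbl))))

  den <- two_round_denoise(pure, blank, sample_tbl, seed = 9)
  ann <- tidy(den)
  round_of <- setNames(ann$removed_round, ann$signal_id)[sample_tbl$signal_id]

  # electrode-migration artifacts are eliminated in round 1
  expect_gte(mean(round_of[pop == "artifact"] == 1, na.rm = TRUE), 0.95)
  expect_lte(mean(is.na(round_of[pop == "artifact"])), 0.05)
  # the contaminant cluster is predominantly removed (either round);
  # residual survivors are the draws that land inside the analyte manifold
  expect_gte(mean(!is.na(round_of[pop == "contaminant"])), 0.6)
  # genuine signals survive
  expect_gte(mean(is.na(round_of[pop == "signal"])), 0.85)
  # per-round provenance is recorded for every removed row
  expect_true(all(ann$removed_round %in% c(1L, 2L, NA_integer_)))

  # determinism of the survivor set
  den2 <- two_round_denoise(pure, blank, sample_tbl, seed = 9)
  expect_identical(den$survivors$signal_id, den2$survivors$signal_id)
})
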