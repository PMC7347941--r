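pu_feature_cols_default <- function() {
  c(feature_current_cols(), "dwell_time_s", "fluctuation_factor")
}

#' Fit a positive-unlabeled (PU) noise filter
#'
#' Learns to separate genuine molecular signals from noise when only a
#' positively labeled set (e.g. pure-solution signals) and an unlabeled set
#' (sample plus blank measurements, a mixture of signal and noise) are
#' available. A gradient-boosted tree classifier is trained to discriminate
#' positive vs unlabeled rows; the label frequency
#' `c = P(labeled | positive)` is then estimated as the mean predicted
#' probability on a held-out fraction of the positives (the Elkan-Noto
#' estimator), and corrected signal scores are `s(x) = p(x) / c`, clipped to
#' `[0, 1]`. Rows with `s >= decision_threshold` are treated as signal.
#'
#' @param positives,unlabeled Feature tables (>= 20 rows each, identical
#'   feature columns).
#' @param seed Integer seed (holdout split and booster).
#' @param decision_threshold Corrected-score cut for keeping a row.
#' @param holdout_frac Fraction of positives held out for calibration.
#' @param feature_cols Feature columns used by the discriminator; defaults
#'   to `I1..I10`, dwell time and fluctuation factor.
#' @param nrounds,max_depth,eta,min_child_weight,subsample Booster
#'   hyperparameters. The defaults are deliberately low-capacity (shallow
#'   trees, strong leaf regularization, row subsampling): the Elkan-Noto
#'   correction needs `p(x)` to estimate class-conditional structure, and a
#'   high-capacity booster memorizes its own unlabeled training rows, biasing
#'   their scores toward zero.
#' @return A `pu_model` object.
#' @export
fit_pu <- function(positives, unlabeled, seed = 1L, decision_threshold = 0.5,
                   holdout_frac = 0.2,
                   feature_cols = pu_feature_cols_default(),
                   nrounds = 50, max_depth = 2, eta = 0.1,
                   min_child_weight = 20, subsample = 0.7) {
  positives <- validate_feature_table(positives)
  unlabeled <- validate_feature_table(unlabeled)
  if (nrow(positives) < 20 || nrow(unlabeled) < 20) {
    stop_nanosig("PU fitting needs >= 20 positive and >= 20 unlabeled rows",
      "nanosig_config_error")
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop_nanosig("decision_threshold must lie in (0, 1)",
      "nanosig_config_error")
  }
  xp <- as.matrix(positives[, feature_cols])
  xu <- as.matrix(unlabeled[, feature_cols])
  if (nrow(xp) == nrow(xu) &&
      isTRUE(all.equal(xp[order(xp[, 1]), ], xu[order(xu[, 1]), ],
        check.attributes = FALSE))) {
    stop_nanosig(
      "positive and unlabeled tables are identical: label frequency is not identifiable",
      "nanosig_calibration_error"
    )
  }
  with_seed(seed, {
    n_hold <- max(1L, round(holdout_frac * nrow(xp)))
    hold <- sample(nrow(xp), n_hold)
    xtrain <- rbind(xp[-hold, , drop = FALSE], xu)
    ytrain <- c(rep(1, nrow(xp) - n_hold), rep(0, nrow(xu)))
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
        eta = eta, min_child_weight = min_child_weight,
        subsample = subsample, nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(xtrain, label = ytrain, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    c_hat <- mean(predict(booster, xp[hold, , drop = FALSE]))
    if (!is.finite(c_hat) || c_hat < 1e-6) {
      stop_nanosig("PU calibration failed: held-out positives scored ~0",
        "nanosig_calibration_error")
    }
    structure(
      list(
        booster = booster, label_frequency_c = c_hat,
        decision_threshold = decision_threshold,
        feature_cols = feature_cols, seed = as.integer(seed),
        n_positive = nrow(positives), n_unlabeled = nrow(unlabeled)
      ),
      class = "pu_model"
    )
  })
}

#' @export
print.pu_model <- function(x, ...) {
  cat(sprintf(
    "<pu_model> c = %.3f, threshold = %.2f (n+ = %d, n? = %d)\n",
    x$label_frequency_c, x$decision_threshold, x$n_positive, x$n_unlabeled
  ))
  invisible(x)
}

#' Corrected PU signal scores
#'
#' @param model A [fit_pu()] model.
#' @param table A feature table.
#' @return Numeric vector of corrected scores in `[0, 1]`.
#' @export
pu_scores <- function(model, table) {
  stopifnot(inherits(model, "pu_model"))
  table <- validate_feature_table(table)
  if (!nrow(table)) return(numeric())
  p <- predict(model$booster, as.matrix(table[, model$feature_cols]))
  pmin(1, pmax(0, p / model$label_frequency_c))
}

#' Estimated positive fraction of an unlabeled set
#'
#' Mean corrected score: under the PU model this estimates the proportion of
#' genuine signal rows in a mixed set.
#'
#' @inheritParams pu_scores
#' @return Scalar in `[0, 1]`.
#' @export
estimate_positive_fraction <- function(model, table) {
  mean(pu_scores(model, table))
}

#' Partition candidate rows into kept signal and removed noise
#'
#' Exhaustive, disjoint split of the candidate table by the corrected PU
#' score at the model's decision threshold. Idempotent: re-filtering the
#' kept rows removes nothing.
#'
#' @inheritParams pu_scores
#' @param candidates A feature table.
#' @return A list with feature tables `kept` and `removed`, each carrying a
#'   `pu_score` column.
#' @export
score_and_filter <- function(model, candidates) {
  candidates <- validate_feature_table(candidates)
  s <- pu_scores(model, candidates)
  scored <- mutate(candidates, pu_score = s)
  list(
    kept = filter(scored, .data$pu_score >= model$decision_threshold),
    removed = filter(scored, .data$pu_score < model$decision_threshold)
  )
}

#' Two-round PU noise removal for tissue-like samples
#'
#' Round 1 trains a PU filter with the pure-solution signals as positives
#' and the blank plus sample measurements as unlabeled, and removes
#' electrode-migration-like noise from the sample (such noise appears even
#' in blank runs). Round 2 retrains with the round-1 sample survivors as
#' positives and the round-1 removals as unlabeled — the first round's role
#' is to furnish in-sample signal training data — and re-filters the
#' survivors, targeting contaminant signals specific to the biological
#' matrix. If round 1 removes fewer rows than a PU fit needs (< 20), round
#' 2 is skipped and flagged.
#'
#' @param pure_signals Feature table of pure-solution signals (positives).
#' @param blank_signals Feature table from blank measurements.
#' @param sample_signals Feature table from the sample to be cleaned.
#' @param seed Integer seed (round 2 derives its own from it).
#' @param ... Passed to [fit_pu()] (threshold, hyperparameters, columns).
#' @return A `pu_denoise_result`: `survivors` (round-2 survivors),
#'   `annotated` (every sample row with `pu_round1_score`,
#'   `pu_round2_score`, and `removed_round` NA/1/2), the two fitted models,
#'   and `round2_skipped`.
#' @export
two_round_denoise <- function(pure_signals, blank_signals, sample_signals,
                              seed = 1L, ...) {
  pure_signals <- validate_feature_table(pure_signals)
  blank_signals <- validate_feature_table(blank_signals)
  sample_signals <- validate_feature_table(sample_signals)
  if (!nrow(pure_signals) || !nrow(blank_signals) || !nrow(sample_signals)) {
    stop_nanosig("all of pure, blank and sample tables must be non-empty",
      "nanosig_config_error")
  }
  m1 <- fit_pu(pure_signals, bind_rows(blank_signals, sample_signals),
    seed = seed, ...)
  r1 <- score_and_filter(m1, sample_signals)
  if (!nrow(r1$kept)) {
    stop_nanosig(
      "round 1 removed every sample row; review the decision threshold",
      "nanosig_pipeline_error"
    )
  }
  round2_skipped <- nrow(r1$removed) < 20
  if (round2_skipped) {
    m2 <- NULL
    kept2 <- r1$kept
    removed2 <- r1$kept[0, ]
  } else {
    m2 <- fit_pu(select(r1$kept, -"pu_score"), select(r1$removed, -"pu_score"),
      seed = seed + 1L, ...)
    r2 <- score_and_filter(m2, select(r1$kept, -"pu_score"))
    kept2 <- r2$kept
    removed2 <- r2$removed
  }
  annotated <- mutate(sample_signals,
    pu_round1_score = pu_scores(m1, sample_signals),
    pu_round2_score = if (is.null(m2)) NA_real_ else
      pu_scores(m2, sample_signals),
    removed_round = dplyr::case_when(
      .data$signal_id %in% r1$removed$signal_id ~ 1L,
      .data$signal_id %in% removed2$signal_id ~ 2L,
      TRUE ~ NA_integer_
    )
  )
  structure(
    list(
      survivors = select(kept2, -"pu_score"),
      annotated = annotated,
      model_round1 = m1, model_round2 = m2,
      round2_skipped = round2_skipped
    ),
    class = "pu_denoise_result"
  )
}

#' @export
print.pu_denoise_result <- function(x, ...) {
  a <- x$annotated
  cat(sprintf(
    "<pu_denoise_result> %d sample rows: removed %d (round 1) + %d (round 2), kept %d%s\n",
    nrow(a), sum(a$removed_round == 1, na.rm = TRUE),
    sum(a$removed_round == 2, na.rm = TRUE), nrow(x$survivors),
    if (x$round2_skipped) " [round 2 skipped]" else ""
  ))
  invisible(x)
}

#' @rdname two_round_denoise
#' @param x A `pu_denoise_result`.
#' @method tidy pu_denoise_result
#' @export
tidy.pu_denoise_result <- function(x, ...) x$annotated

#' @rdname two_round_denoise
#' @method glance pu_denoise_result
#' @export
glance.pu_denoise_result <- function(x, ...) {
  a <- x$annotated
  tibble(
    n_sample = nrow(a),
    removed_round1 = sum(a$removed_round == 1, na.rm = TRUE),
    removed_round2 = sum(a$removed_round == 2, na.rm = TRUE),
    kept = nrow(x$survivors),
    round2_skipped = x$round2_skipped
  )
}
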