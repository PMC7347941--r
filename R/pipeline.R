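#' Pipeline configuration
#'
#' Bundles the paths and stage settings for the full workflow: train on
#' pure-solution traces, denoise a sample with two-round PU filtering,
#' classify each surviving signal, and aggregate into a vote and a mixture
#' estimate. All stochastic stages derive their seeds from the single
#' global `seed`.
#'
#' @param pure_traces Named list, one entry per analyte class
#'   (`DA`/`NE`/`5HT`), each a character vector of trace-file paths.
#' @param blank_traces Character vector of blank (no-analyte) trace paths.
#' @param sample_traces Character vector of sample trace paths.
#' @param out_dir Output directory for intermediates and reports.
#' @param seed Global integer seed.
#' @param detection List of [detection_params()] overrides.
#' @param pu List of [fit_pu()] overrides (e.g. `decision_threshold`);
#'   `prefilter = TRUE` additionally PU-filters the pure-solution features
#'   against the blank before training.
#' @param classifier List of classifier hyperparameter overrides; may also
#'   carry `feature_cols`. The pipeline default adds the fluctuation factor
#'   to the ten region currents — on trace-derived features the explicit
#'   fluctuation statistic recovers the class separation that per-region
#'   observation noise otherwise blurs.
#' @param cv_folds Cross-validation folds (default 10).
#' @param vote_tie_rule Tie rule for the final vote.
#' @return A validated `nanosig_pipeline_config` list.
#' @export
pipeline_config <- function(pure_traces, blank_traces, sample_traces,
                            out_dir, seed = 1L, detection = list(),
                            pu = list(), classifier = list(), cv_folds = 10,
                            vote_tie_rule = "lexicographic") {
  config <- structure(
    list(
      pure_traces = pure_traces, blank_traces = blank_traces,
      sample_traces = sample_traces, out_dir = out_dir,
      seed = as.integer(seed), detection = detection, pu = pu,
      classifier = classifier, cv_folds = cv_folds,
      vote_tie_rule = vote_tie_rule
    ),
    class = "nanosig_pipeline_config"
  )
  validate_pipeline_config(config)
}

validate_pipeline_config <- function(config) {
  if (!length(config$pure_traces) || is.null(names(config$pure_traces))) {
    stop_nanosig("pure_traces must be a named list of per-class trace paths",
      "nanosig_config_error")
  }
  bad <- setdiff(names(config$pure_traces), NANOSIG_CLASSES)
  if (length(bad)) {
    stop_nanosig(sprintf("unknown pure-trace classes: %s",
      paste(bad, collapse = ", ")), "nanosig_config_error")
  }
  paths <- c(unlist(config$pure_traces), config$blank_traces,
    config$sample_traces)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_nanosig(sprintf("missing trace files: %s",
      paste(missing, collapse = ", ")), "nanosig_config_error")
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; relative trace paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `nanosig_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  pipeline_config(
    pure_traces = lapply(raw$pure_traces, resolve),
    blank_traces = resolve(unlist(raw$blank_traces)),
    sample_traces = resolve(unlist(raw$sample_traces)),
    out_dir = raw$out_dir %||% file.path(base, "nanosig_out"),
    seed = raw$seed %||% 1L,
    detection = raw$detection %||% list(),
    pu = raw$pu %||% list(),
    classifier = raw$classifier %||% list(),
    cv_folds = raw$cv_folds %||% 10,
    vote_tie_rule = raw$vote_tie_rule %||% "lexicographic"
  )
}

config_detection_params <- function(config) {
  do.call(detection_params, config$detection)
}

detect_and_featurize <- function(paths, config, label, id_prefix) {
  params <- config_detection_params(config)
  feats <- imap(paths, function(path, i) {
    trace <- read_trace(path)
    pulses <- detect_pulses(trace, params,
      source_trace_id = sprintf("%s%02d", id_prefix, as.integer(i)))
    extract_features(pulses, label = label)
  })
  out <- list_rbind(unname(feats))
  mutate(out, signal_id = sprintf("%s_%05d", id_prefix, row_number()))
}

manifest_write <- function(path, config, stage_counts, extra = list()) {
  manifest <- c(
    list(
      schema_version = "nanosig_manifest_v1",
      package_version = as.character(utils::packageVersion("nanosig")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      stage_counts = stage_counts
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Run the training stage of the pipeline
#'
#' For each analyte class, reads the pure-solution traces, detects and
#' featurizes their pulses; optionally PU-filters them against the blank
#' features; reports stratified k-fold cross-validation; and fits the final
#' classifier on all labeled features. All intermediates are written under
#' `config$out_dir` with a manifest (config hash, seed, per-stage counts)
#' sufficient to reproduce the run.
#'
#' @param config A [pipeline_config()].
#' @return A `nanosig_training` list: `model`, `report` (a `cv_report`),
#'   `pure_features`, `blank_features`, `out_dir`.
#' @export
run_training <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pure <- imap(config$pure_traces, function(paths, class) {
    detect_and_featurize(paths, config, label = class,
      id_prefix = paste0("pure_", class))
  })
  pure <- list_rbind(unname(pure))
  blank <- detect_and_featurize(config$blank_traces, config,
    label = "NOISE", id_prefix = "blank")
  n_raw <- nrow(pure)
  pu_args <- config$pu
  prefilter <- isTRUE(pu_args$prefilter)
  pu_args$prefilter <- NULL
  if (prefilter && nrow(blank) >= 20 && nrow(pure) >= 20) {
    flt <- do.call(fit_pu, c(list(positives = pure, unlabeled = blank,
      seed = config$seed), pu_args))
    pure <- select(score_and_filter(flt, pure)$kept, -"pu_score")
  }
  cls_args <- config$classifier
  cls_cols <- cls_args$feature_cols %||%
    c(feature_current_cols(), "fluctuation_factor")
  cls_args$feature_cols <- NULL
  report <- cross_validate(pure, k = config$cv_folds,
    hyperparams = cls_args, seed = config$seed, feature_cols = cls_cols)
  model <- train_classifier(pure, hyperparams = cls_args,
    seed = config$seed, feature_cols = cls_cols)
  write_feature_table(pure, file.path(config$out_dir, "pure_features.csv"))
  write_feature_table(blank, file.path(config$out_dir, "blank_features.csv"))
  jsonlite::write_json(
    list(
      schema_version = "nanosig_cv_report_v1",
      classes = report$classes, k = report$k,
      macro_f_mean = report$macro_f_mean, macro_f_sd = report$macro_f_sd,
      macro_f_folds = report$macro_f,
      confusion_mean = report$confusion_mean,
      confusion_sd = report$confusion_sd
    ),
    file.path(config$out_dir, "cv_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  saveRDS(model, file.path(config$out_dir, "model.rds"))
  manifest_write(
    file.path(config$out_dir, "training_manifest.json"), config,
    stage_counts = list(
      pure_signals_detected = n_raw,
      pure_signals_after_prefilter = nrow(pure),
      blank_signals_detected = nrow(blank),
      per_class = as.list(table(pure$label))
    )
  )
  structure(
    list(model = model, report = report, pure_features = pure,
      blank_features = blank, out_dir = config$out_dir),
    class = "nanosig_training"
  )
}

#' Run the sample-analysis stage of the pipeline
#'
#' Reads the sample traces, detects and featurizes their pulses, removes
#' noise with [two_round_denoise()] (pure-solution positives, blank +
#' sample unlabeled), classifies each surviving signal, and aggregates the
#' predictions into a majority vote and a mixture estimate. The manifest
#' records the count at every filtering stage, and
#' `detected = removed round 1 + removed round 2 + classified` always
#' holds. Zero surviving signals yields an explicit empty-result status.
#'
#' @param config A [pipeline_config()].
#' @param training A `nanosig_training` from [run_training()] (carries the
#'   classifier plus the pure/blank feature tables the denoiser needs).
#' @return A `nanosig_sample_result` list: `status` (`"ok"` or `"empty"`),
#'   `mixture` (a `mixture_estimate`), `vote` (a `vote_result`),
#'   `per_signal` prediction table, `denoise` (a `pu_denoise_result`) and
#'   `stage_counts`.
#' @export
run_sample_analysis <- function(config, training) {
  config <- validate_pipeline_config(config)
  stopifnot(inherits(training, "nanosig_training"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sample_feats <- detect_and_featurize(config$sample_traces, config,
    label = "UNLABELED", id_prefix = "sample")
  if (!nrow(sample_feats)) {
    return(empty_sample_result(config, n_detected = 0))
  }
  pu_args <- config$pu
  pu_args$prefilter <- NULL
  pure <- filter(training$pure_features, .data$label %in% NANOSIG_CLASSES)
  den <- do.call(two_round_denoise, c(
    list(pure_signals = pure, blank_signals = training$blank_features,
      sample_signals = sample_feats, seed = config$seed),
    pu_args
  ))
  if (!nrow(den$survivors)) {
    return(empty_sample_result(config, n_detected = nrow(sample_feats)))
  }
  pred <- predict_labels(training$model, den$survivors)
  vote <- majority_vote(pred$.pred_class, tie_rule = config$vote_tie_rule,
    seed = config$seed)
  mixture <- estimate_mixture(pred$.pred_class,
    classes = training$model$classes)
  g <- glance(den)
  stage_counts <- list(
    detected = nrow(sample_feats),
    removed_round1 = g$removed_round1,
    removed_round2 = g$removed_round2,
    classified = nrow(pred),
    per_class = as.list(table(factor(pred$.pred_class,
      levels = training$model$classes)))
  )
  write_feature_table(sample_feats,
    file.path(config$out_dir, "sample_features.csv"))
  write_feature_table(den$survivors,
    file.path(config$out_dir, "denoised_features.csv"))
  readr::write_csv(select(pred, "signal_id", "source_trace_id",
    ".pred_class", dplyr::starts_with(".prob_")),
    file.path(config$out_dir, "per_signal_predictions.csv"))
  jsonlite::write_json(
    list(
      schema_version = "nanosig_result_v1", status = "ok",
      counts = stage_counts,
      ratios = setNames(as.list(mixture$composition$ratio),
        mixture$composition$class),
      ternary = as.list(mixture$ternary),
      vote_winner = vote$winner, vote_tie = vote$tie
    ),
    file.path(config$out_dir, "result.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest_write(file.path(config$out_dir, "sample_manifest.json"), config,
    stage_counts = stage_counts)
  structure(
    list(status = "ok", mixture = mixture, vote = vote, per_signal = pred,
      denoise = den, stage_counts = stage_counts),
    class = "nanosig_sample_result"
  )
}

empty_sample_result <- function(config, n_detected) {
  stage_counts <- list(detected = n_detected, removed_round1 = n_detected,
    removed_round2 = 0L, classified = 0L)
  jsonlite::write_json(
    list(schema_version = "nanosig_result_v1", status = "empty",
      counts = stage_counts),
    file.path(config$out_dir, "result.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  structure(
    list(status = "empty", mixture = NULL, vote = NULL,
      per_signal = NULL, denoise = NULL, stage_counts = stage_counts),
    class = "nanosig_sample_result"
  )
}

#' @export
print.nanosig_sample_result <- function(x, ...) {
  if (x$status == "empty") {
    cat("<nanosig_sample_result> empty: no signals survived filtering\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<nanosig_sample_result> %d detected -> %d + %d removed -> %d classified; winner %s\n",
    x$stage_counts$detected, x$stage_counts$removed_round1,
    x$stage_counts$removed_round2, x$stage_counts$classified,
    x$vote$winner
  ))
  invisible(x)
}
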