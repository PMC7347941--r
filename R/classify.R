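#' Train the supervised single-signal classifier
#'
#' Gradient-boosted decision-tree ensemble (multiclass softprob) on the ten
#' region currents `I1..I10`; dwell time and fluctuation factor can be added
#' via `feature_cols`. The `NOISE` and `UNLABELED` bookkeeping labels are
#' never classes: noise is handled upstream by PU removal.
#'
#' @param train Labeled feature table (>= 2 classes, >= 10 rows per class).
#' @param hyperparams List with `nrounds`, `max_depth`, `eta` (defaults 500,
#'   4, 0.1).
#' @param seed Integer seed; training is deterministic under it.
#' @param feature_cols Feature columns (default `I1..I10`).
#' @return A `nanosig_classifier`.
#' @export
train_classifier <- function(train, hyperparams = list(), seed = 1L,
                             feature_cols = feature_current_cols()) {
  train <- validate_feature_table(train)
  train <- filter(train, .data$label %in% NANOSIG_CLASSES)
  hp <- utils::modifyList(list(nrounds = 500, max_depth = 4, eta = 0.1),
    hyperparams)
  classes <- sort(unique(train$label))
  if (length(classes) < 2) {
    stop_nanosig("training needs at least 2 analyte classes",
      "nanosig_config_error")
  }
  n_per <- table(train$label)
  if (any(n_per < 10)) {
    stop_nanosig(
      sprintf("every class needs >= 10 rows (got %s)",
        paste(names(n_per), n_per, sep = "=", collapse = ", ")),
      "nanosig_config_error"
    )
  }
  y <- match(train$label, classes) - 1L
  with_seed(seed, {
    booster <- xgboost::xgb.train(
      params = list(
        objective = "multi:softprob", num_class = length(classes),
        max_depth = hp$max_depth, eta = hp$eta, nthread = 1,
        seed = as.integer(seed)
      ),
      data = xgboost::xgb.DMatrix(as.matrix(train[, feature_cols]),
        label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0
    )
    structure(
      list(booster = booster, classes = classes,
        feature_cols = feature_cols, hyperparams = hp,
        seed = as.integer(seed)),
      class = "nanosig_classifier"
    )
  })
}

#' @export
print.nanosig_classifier <- function(x, ...) {
  cat(sprintf(
    "<nanosig_classifier> classes: %s; %d trees x depth %d, eta %g\n",
    paste(x$classes, collapse = "/"), x$hyperparams$nrounds,
    x$hyperparams$max_depth, x$hyperparams$eta
  ))
  invisible(x)
}

#' Classify feature vectors one signal at a time
#'
#' @param model A [train_classifier()] model.
#' @param features A feature table.
#' @return The input with `.pred_class` (argmax label) and one `.prob_<class>`
#'   column per class; probabilities sum to 1 per row.
#' @export
predict_labels <- function(model, features) {
  stopifnot(inherits(model, "nanosig_classifier"))
  features <- validate_feature_table(features)
  prob_cols <- paste0(".prob_", model$classes)
  if (!nrow(features)) {
    out <- features
    out$.pred_class <- character()
    for (pc in prob_cols) out[[pc]] <- numeric()
    return(out)
  }
  missing <- setdiff(model$feature_cols, names(features))
  if (length(missing)) {
    stop_nanosig(
      sprintf("feature table lacks model columns: %s",
        paste(missing, collapse = ", ")),
      "nanosig_schema_error"
    )
  }
  p <- predict(model$booster, as.matrix(features[, model$feature_cols]))
  p <- matrix(p, ncol = length(model$classes))
  colnames(p) <- prob_cols
  out <- mutate(features,
    .pred_class = model$classes[max.col(p, ties.method = "first")])
  bind_cols(out, as_tibble(p))
}

#' Stratified k-fold cross-validated classification report
#'
#' Stratified fold assignment per class, one model per fold; per-fold
#' row-normalized confusion matrices (rows = true class) are averaged, and
#' the macro F-measure (unweighted mean of per-class F1) is reported as mean
#' +/- sd over folds.
#'
#' @param data Labeled feature table.
#' @param k Number of folds (default 10).
#' @inheritParams train_classifier
#' @return A `cv_report`: `confusion_mean`, `confusion_sd`, per-fold
#'   matrices, `macro_f` per fold with mean/sd, and per-class
#'   precision/recall means.
#' @export
cross_validate <- function(data, k = 10, hyperparams = list(), seed = 1L,
                           feature_cols = feature_current_cols()) {
  data <- validate_feature_table(data)
  data <- filter(data, .data$label %in% NANOSIG_CLASSES)
  classes <- sort(unique(data$label))
  if (k < 2) stop_nanosig("k must be >= 2", "nanosig_config_error")
  if (any(table(data$label) < k)) {
    stop_nanosig("every class needs >= k rows for stratified folds",
      "nanosig_config_error")
  }
  folds <- with_seed(seed, {
    f <- integer(nrow(data))
    for (cl in classes) {
      idx <- which(data$label == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  fold_out <- map(seq_len(k), function(fold) {
    train <- data[folds != fold, ]
    test <- data[folds == fold, ]
    model <- train_classifier(train, hyperparams = hyperparams,
      seed = seed + fold, feature_cols = feature_cols)
    pred <- predict_labels(model, test)
    cm <- table(
      factor(test$label, levels = classes),
      factor(pred$.pred_class, levels = classes)
    )
    list(confusion = unclass(cm), macro_f = macro_f_from_counts(cm))
  })
  conf_counts <- map(fold_out, "confusion")
  conf_norm <- map(conf_counts, function(m) m / pmax(1, rowSums(m)))
  arr <- simplify2array(conf_norm)
  structure(
    list(
      classes = classes, k = k,
      fold_confusion = conf_counts,
      confusion_mean = apply(arr, 1:2, mean),
      confusion_sd = apply(arr, 1:2, sd),
      macro_f = map_dbl(fold_out, "macro_f"),
      macro_f_mean = mean(map_dbl(fold_out, "macro_f")),
      macro_f_sd = sd(map_dbl(fold_out, "macro_f")),
      per_class = per_class_from_counts(Reduce(`+`, conf_counts), classes)
    ),
    class = "cv_report"
  )
}

# Macro F1 from a confusion matrix of counts (rows = truth).
macro_f_from_counts <- function(cm) {
  cm <- unclass(cm)
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

per_class_from_counts <- function(cm, classes) {
  tibble(
    class = classes,
    precision = vapply(seq_along(classes), function(i) {
      if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else NA_real_
    }, numeric(1)),
    recall = vapply(seq_along(classes), function(i) {
      if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else NA_real_
    }, numeric(1))
  )
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report> %d-fold CV, macro F = %.2f +/- %.2f\n",
    x$k, x$macro_f_mean, x$macro_f_sd))
  cat("row-normalized confusion (mean over folds):\n")
  print(round(x$confusion_mean, digits))
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' `tidy()` returns the mean row-normalized confusion matrix in long form;
#' `glance()` returns a one-row summary with the macro F-measure.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  cm <- x$confusion_mean
  sdm <- x$confusion_sd
  out <- tidyr::expand_grid(truth = x$classes, prediction = x$classes)
  mutate(out,
    mean = purrr::map2_dbl(.data$truth, .data$prediction,
      function(t, p) cm[t, p]),
    sd = purrr::map2_dbl(.data$truth, .data$prediction,
      function(t, p) sdm[t, p])
  )
}

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    k = x$k, macro_f = x$macro_f_mean, macro_f_sd = x$macro_f_sd,
    accuracy = sum(diag(Reduce(`+`, x$fold_confusion))) /
      sum(Reduce(`+`, x$fold_confusion))
  )
}

#' Expected macro F of a uniform random classifier
#'
#' On balanced classes a uniform random predictor has precision = recall =
#' `1/n_classes` for every class, hence macro F `1/n_classes` — the chance
#' baseline (0.33 for the three analytes).
#'
#' @param n_classes Number of classes (>= 2).
#' @return `1 / n_classes`.
#' @export
random_baseline_f <- function(n_classes) {
  stopifnot(n_classes >= 2)
  1 / n_classes
}
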