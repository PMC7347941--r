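#' Plot a current-time trace with optional detected pulses
#'
#' @param trace A [current_trace()].
#' @param pulses Optional pulse tibble from [detect_pulses()]; detected
#'   spans are shaded.
#' @param downsample Plot every k-th sample for long traces (default keeps
#'   at most ~2e5 points).
#' @return A ggplot.
#' @export
plot_trace <- function(trace, pulses = NULL, downsample = NULL) {
  stopifnot(inherits(trace, "nanosig_trace"))
  k <- downsample %||% max(1L, nrow(trace) %/% 2e5)
  dat <- as_tibble(trace)[seq(1, nrow(trace), by = k), ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s,
    y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
  if (!is.null(pulses) && nrow(pulses)) {
    fs <- trace_sampling_rate(trace)
    spans <- tibble(xmin = pulses$start_sample / fs,
      xmax = pulses$end_sample / fs)
    p <- p + ggplot2::geom_rect(
      data = spans,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
        ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.25
    )
  }
  p
}

#' Per-class current-amplitude histograms
#'
#' @param features A labeled feature table.
#' @param bin_size Bin width in pA.
#' @return A ggplot.
#' @export
plot_current_histogram <- function(features, bin_size = 1) {
  features <- validate_feature_table(features)
  dat <- mutate(features, mean_current = signal_mean_currents(features))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_current,
    fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = bin_size, boundary = 0,
      position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "mean signal current (pA)", y = "count",
      fill = "analyte")
}

#' Fluctuation-factor density per class
#'
#' Kernel density estimates (Scott bandwidth) of the current fluctuation
#' factor for each label, the view in which the analytes order
#' 5-HT > DA > NE.
#'
#' @param features A labeled feature table.
#' @return A ggplot.
#' @export
plot_fluctuation_density <- function(features) {
  features <- validate_feature_table(features)
  dens <- features |>
    group_by(.data$label) |>
    dplyr::group_modify(~ kde_density(.x$fluctuation_factor)) |>
    ungroup()
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fluctuation factor", y = "probability density",
      colour = "analyte")
}

#' @describeIn cross_validate Confusion-matrix heat map (mean +/- sd over
#'   folds).
#' @param object A `cv_report`.
#' @param ... Unused.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$prediction, y = .data$truth,
    fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f±%.2f", .data$mean, .data$sd))) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
      limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true", fill = "ratio")
}

ternary_triangle_data <- function(classes) {
  tibble(
    x = c(0, 1, 0.5, 0),
    y = c(0, 0, sqrt(3) / 2, 0),
    label = c(classes, classes[1])
  )
}

#' Ternary plot of mixture estimates
#'
#' @param object A `mixture_estimate` (three classes).
#' @param truth Optional true composition triple to overlay as a dot.
#' @param ... Unused.
#' @method autoplot mixture_estimate
#' @export
autoplot.mixture_estimate <- function(object, truth = NULL, ...) {
  if (is.null(object$ternary)) {
    stop_nanosig("ternary plots need exactly three classes",
      "nanosig_domain_error")
  }
  classes <- object$composition$class
  tri <- ternary_triangle_data(classes)
  verts <- tri[1:3, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = verts, ggplot2::aes(x = .data$x, y = .data$y,
      label = .data$label), vjust = c(1.6, 1.6, -0.8)) +
    ggplot2::geom_point(data = object$ternary, ggplot2::aes(x = .data$x,
      y = .data$y), shape = 18, size = 4, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(data = ternary_coordinates(truth),
      ggplot2::aes(x = .data$x, y = .data$y), size = 2, colour = "black")
  }
  p
}
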