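#' Ten-region feature extraction
#'
#' Each detected pulse is divided into 10 contiguous equal-duration regions
#' along the time axis; the feature vector is the arithmetic mean of the
#' baseline-subtracted current in each region (`I1..I10`, pA). When the
#' pulse length is not divisible by 10, the leading regions take one extra
#' sample each, so every sample belongs to exactly one region. The derived
#' fluctuation factor `(max_j I_j - mean_j I_j) / mean_j I_j` is attached
#' along with the dwell time.
#'
#' @param pulses A pulse tibble from [detect_pulses()].
#' @param label Optional label for all rows (default `"UNLABELED"`).
#' @param baseline_subtract Subtract the per-pulse local baseline before
#'   averaging (default `TRUE`; features are then gap-width-robust).
#' @return A validated feature table (see [validate_feature_table()]).
#' @export
extract_features <- function(pulses, label = "UNLABELED",
                             baseline_subtract = TRUE) {
  stopifnot(label %in% NANOSIG_LABELS)
  if (!nrow(pulses)) {
    empty <- matrix(numeric(), 0, 10,
      dimnames = list(NULL, feature_current_cols()))
    return(validate_feature_table(bind_cols(
      tibble(signal_id = character(), source_trace_id = character()),
      as_tibble(empty),
      tibble(dwell_time_s = numeric(), fluctuation_factor = numeric(),
        label = character())
    )))
  }
  regions <- map(seq_len(nrow(pulses)), function(i) {
    s <- pulses$samples_pA[[i]]
    if (baseline_subtract) s <- s - pulses$baseline_pA[i]
    region_currents(s)
  })
  regions <- do.call(rbind, regions)
  colnames(regions) <- feature_current_cols()
  out <- bind_cols(
    tibble(signal_id = pulses$signal_id,
      source_trace_id = pulses$source_trace_id),
    as_tibble(regions),
    tibble(
      dwell_time_s = pulses$dwell_time_s,
      fluctuation_factor = apply(regions, 1, fluctuation_factor),
      label = label
    )
  )
  validate_feature_table(out)
}

# Mean current in each of 10 contiguous regions; remainder samples go one
# each to the leading regions.
region_currents <- function(samples) {
  n <- length(samples)
  if (n < 10) {
    stop_nanosig(
      sprintf("pulse has %d samples; ten-region features need >= 10", n),
      "nanosig_feature_error"
    )
  }
  as.numeric(tapply(samples, region_assignment(n, 10L), mean))
}

#' Current fluctuation factor
#'
#' `(max I_j - mean I_j) / mean I_j` over the ten region currents: a
#' scale-invariant measure of intra-pulse current variability that separates
#' the analytes in the order 5-HT > DA > NE. Zero iff all regions are equal.
#'
#' @param I Numeric vector of region currents (typically length 10), or a
#'   one-row slice of a feature table.
#' @return Dimensionless scalar >= 0.
#' @examples
#' fluctuation_factor(c(22.1, 20.8, 27.6, 23.7, 23.5, 21.4, 19.5, 28.8, 26.8, 31.3))
#' @export
fluctuation_factor <- function(I) {
  if (is.data.frame(I)) I <- as.numeric(I[1, feature_current_cols()])
  m <- mean(I)
  if (m <= 0) {
    stop_nanosig("fluctuation factor needs a positive mean region current",
      "nanosig_domain_error")
  }
  (max(I) - m) / m
}

#' Histogram of per-signal mean currents
#'
#' Counts per-signal mean currents in fixed-width bins anchored at 0
#' (half-open `[k*bin, (k+1)*bin)`), the representation used for
#' current-amplitude histograms of each analyte.
#'
#' @param x A feature table (mean of `I1..I10` per row), a pulse tibble
#'   (mean baseline-subtracted current per pulse), or a numeric vector of
#'   mean currents in pA.
#' @param bin_size Bin width in pA (default 1).
#' @return A tibble `bin_left`, `bin_right`, `count` (empty input gives an
#'   empty tibble).
#' @export
current_histogram <- function(x, bin_size = 1) {
  stopifnot(bin_size > 0)
  v <- signal_mean_currents(x)
  if (!length(v)) {
    return(tibble(bin_left = numeric(), bin_right = numeric(),
      count = integer()))
  }
  idx <- floor(v / bin_size)
  tab <- count(tibble(idx = idx), .data$idx)
  tibble(
    bin_left = tab$idx * bin_size,
    bin_right = (tab$idx + 1) * bin_size,
    count = as.integer(tab$n)
  )
}

signal_mean_currents <- function(x) {
  if (is.numeric(x)) return(x)
  x <- as_tibble(x)
  if (all(feature_current_cols() %in% names(x))) {
    return(rowMeans(x[, feature_current_cols()]))
  }
  if (all(c("samples_pA", "baseline_pA") %in% names(x))) {
    return(map_dbl(seq_len(nrow(x)), function(i) {
      mean(x$samples_pA[[i]] - x$baseline_pA[i])
    }))
  }
  stop_nanosig("cannot derive mean currents from this input",
    "nanosig_schema_error")
}

#' Gaussian kernel density estimate on a grid
#'
#' Wraps [stats::density()] with Scott's rule-of-thumb bandwidth
#' ([stats::bw.nrd()]) when none is given. The returned grid density
#' integrates to 1 (trapezoid rule, tolerance 1e-3). Zero-variance input is
#' an error: a kernel density of a degenerate sample is a delta spike, which
#' the grid representation cannot honestly carry.
#'
#' @param values Numeric vector, length >= 2.
#' @param bandwidth Optional kernel bandwidth.
#' @param n_grid Number of grid points.
#' @return A tibble with columns `x` and `density`.
#' @export
kde_density <- function(values, bandwidth = NULL, n_grid = 512) {
  if (length(values) < 2) {
    stop_nanosig("kernel density estimation needs at least 2 values",
      "nanosig_domain_error")
  }
  if (sd(values) == 0) {
    stop_nanosig("zero-variance input: density is a delta spike",
      "nanosig_domain_error")
  }
  bw <- bandwidth %||% bw.nrd(values)
  d <- density(values, bw = bw, n = n_grid, cut = 4)
  tibble(x = d$x, density = d$y)
}

#' Dwell-time summary statistics
#'
#' Median and quartiles of the dwell time per label, plus a log-spaced
#' dwell-time histogram. Labels absent from the input are absent from the
#' summary.
#'
#' @param x A feature table or pulse tibble with `dwell_time_s` (and
#'   optionally `label`).
#' @param n_bins Number of log-spaced histogram bins.
#' @return A list with tibbles `summary` (label, n, q25, median, q75) and
#'   `histogram` (label, bin_left, bin_right, count).
#' @export
dwell_time_summary <- function(x, n_bins = 20) {
  x <- as_tibble(x)
  if (!nrow(x)) {
    stop_nanosig("dwell-time summary needs at least one pulse",
      "nanosig_domain_error")
  }
  if (!"label" %in% names(x)) x$label <- "UNLABELED"
  smry <- summarise(group_by(x, .data$label),
    n = dplyr::n(),
    q25 = quantile(.data$dwell_time_s, 0.25),
    median = median(.data$dwell_time_s),
    q75 = quantile(.data$dwell_time_s, 0.75),
    .groups = "drop"
  )
  rng <- range(x$dwell_time_s)
  if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
  breaks <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  hist <- summarise(
    group_by(x, .data$label,
      bin = cut(.data$dwell_time_s, breaks, include.lowest = TRUE,
        labels = FALSE)),
    count = dplyr::n(), .groups = "drop"
  )
  hist <- mutate(hist,
    bin_left = breaks[.data$bin], bin_right = breaks[.data$bin + 1])
  list(summary = smry,
    histogram = select(hist, "label", "bin_left", "bin_right", "count"))
}
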