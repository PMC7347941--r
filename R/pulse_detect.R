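#' Pulse-detection parameters
#'
#' @param baseline_window Rolling-median window in samples (forced odd).
#' @param threshold_sigma Detection threshold as a multiple of the robust
#'   noise scale.
#' @param min_duration Minimum pulse length in samples; at least 10 so each
#'   pulse supports the ten-region feature split.
#' @param merge_gap Pulses separated by fewer than this many samples are
#'   merged.
#' @param min_core_samples Minimum number of above-threshold samples a
#'   candidate pulse must contain; rejects isolated noise exceedances that
#'   the baseline-return extension would otherwise inflate past
#'   `min_duration`.
#' @return A `nanosig_detection_params` list.
#' @export
detection_params <- function(baseline_window = 1000L, threshold_sigma = 3,
                             min_duration = 10L, merge_gap = 5L,
                             min_core_samples = 3L) {
  stopifnot(baseline_window > 0, threshold_sigma > 0, merge_gap > 0,
    min_core_samples >= 1)
  if (min_duration < 10) {
    stop_nanosig("min_duration must be >= 10 (ten feature regions)",
      "nanosig_config_error")
  }
  structure(
    list(
      baseline_window = as.integer(baseline_window),
      threshold_sigma = threshold_sigma,
      min_duration = as.integer(min_duration),
      merge_gap = as.integer(merge_gap),
      min_core_samples = as.integer(min_core_samples)
    ),
    class = "nanosig_detection_params"
  )
}

#' Estimate the tunnelling baseline and noise scale
#'
#' Rolling-median baseline (window `baseline_window`, median-robust to the
#' sparse pulses riding on top) and a robust noise scale
#' `sigma = 1.4826 * MAD` of the residuals.
#'
#' @param trace A [current_trace()].
#' @param params A [detection_params()].
#' @return A list with `baseline` (pA, per sample) and `noise_sigma` (pA).
#' @export
estimate_baseline <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "nanosig_trace"))
  x <- trace$current_pA
  if (length(x) <= params$baseline_window) {
    stop_nanosig("trace shorter than baseline window", "nanosig_config_error")
  }
  k <- min(params$baseline_window, length(x))
  if (k %% 2 == 0) k <- k - 1L
  baseline <- as.numeric(runmed(x, k, endrule = "median"))
  resid <- x - baseline
  list(baseline = baseline, noise_sigma = mad(resid))
}

#' Detect pulse signals in a trace
#'
#' Marks samples where the baseline-subtracted current exceeds
#' `threshold_sigma * noise_sigma`, extends each excursion outward until the
#' current returns to the baseline (residual <= 0), merges excursions closer
#' than `merge_gap` samples, and drops those shorter than `min_duration` or
#' truncated by the trace edges. Spans are half-open `[start, end)` in
#' 0-based samples and never overlap.
#'
#' @param trace A [current_trace()].
#' @param params A [detection_params()].
#' @param source_trace_id Provenance string for downstream tables.
#' @return A pulse tibble: `signal_id`, `source_trace_id`, `start_sample`,
#'   `end_sample`, `baseline_pA` (local baseline level), `dwell_time_s`, and
#'   the raw samples as a list column `samples_pA`.
#' @export
detect_pulses <- function(trace, params = detection_params(),
                          source_trace_id = "trace") {
  est <- estimate_baseline(trace, params)
  x <- trace$current_pA
  resid <- x - est$baseline
  n <- length(x)
  empty <- tibble(
    signal_id = character(), source_trace_id = character(),
    start_sample = integer(), end_sample = integer(),
    baseline_pA = numeric(), dwell_time_s = numeric(),
    samples_pA = list()
  )
  if (est$noise_sigma == 0) {
    above <- resid > 0
  } else {
    above <- resid > params$threshold_sigma * est$noise_sigma
  }
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values]) # 1-based incl.

  # hysteresis: grow each run outward to the baseline return (resid <= 0)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    while (s > 1 && resid[s - 1] > 0) s <- s - 1L
    e <- runs$end[i]
    while (e < n && resid[e + 1] > 0) e <- e + 1L
    runs$start[i] <- s
    runs$end[i] <- e
  }
  runs <- dplyr::distinct(arrange(runs, .data$start))

  # merge runs separated by < merge_gap samples (also resolves overlaps
  # created by the extension step)
  merged <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap < params$merge_gap) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], runs$end[i])
    } else {
      merged <- bind_rows(merged, runs[i, ])
    }
  }

  merged <- mutate(merged, core = map_dbl(seq_len(nrow(merged)), function(i) {
    sum(above[merged$start[i]:merged$end[i]])
  }))
  merged <- filter(merged,
    .data$end - .data$start + 1L >= params$min_duration,
    .data$core >= params$min_core_samples,
    .data$start > 1L, .data$end < n) # edge-truncated pulses are biased: drop
  if (!nrow(merged)) return(empty)

  fs <- trace_sampling_rate(trace)
  tibble(
    signal_id = sprintf("%s_p%04d", source_trace_id, seq_len(nrow(merged))),
    source_trace_id = source_trace_id,
    start_sample = merged$start - 1L, # half-open 0-based [start, end)
    end_sample = merged$end,
    baseline_pA = map_dbl(seq_len(nrow(merged)), function(i) {
      mean(est$baseline[merged$start[i]:merged$end[i]])
    }),
    dwell_time_s = (merged$end - merged$start + 1L) / fs,
    samples_pA = map(seq_len(nrow(merged)), function(i) {
      x[merged$start[i]:merged$end[i]]
    })
  )
}

#' Gap distance from the baseline tunnelling current
#'
#' Inverts the exponential barrier model
#' `I = G_contact * V * exp(-beta * d)` to
#' `d = ln(G_contact * V / I) / beta`. Strictly decreasing in the baseline
#' current; `d = 0` at the contact limit `I = G_contact * V`.
#'
#' @param baseline_current_pA Baseline current in pA (vectorized).
#' @param bias_voltage Bias in volts.
#' @param decay_per_nm Decay constant beta in 1/nm. The default 10.9/nm is a
#'   conventional vacuum-gap scale and is configurable, not a calibrated
#'   device constant.
#' @param contact_conductance Contact conductance in S (default G0).
#' @return Gap distance in nm.
#' @examples
#' gap_distance_from_baseline(15, 0.1, decay_per_nm = 10)
#' @export
gap_distance_from_baseline <- function(baseline_current_pA, bias_voltage = 0.1,
                                       decay_per_nm = 10.9,
                                       contact_conductance = 7.748e-5) {
  i_max_pA <- contact_conductance * bias_voltage * 1e12
  if (any(baseline_current_pA <= 0) || any(baseline_current_pA > i_max_pA)) {
    stop_nanosig(
      sprintf("baseline current must lie in (0, %.6g] pA (contact limit)",
        i_max_pA),
      "nanosig_domain_error"
    )
  }
  log(i_max_pA / baseline_current_pA) / decay_per_nm
}
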