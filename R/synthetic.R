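#' Per-class single-molecule signal models
#'
#' A signal model describes the statistical behaviour of one analyte's pulse
#' signals: the distribution of the per-pulse mean amplitude (truncated
#' Gaussian, pA), the intra-pulse fluctuation scale (dimensionless
#' multiplicative variability across a pulse), a log-normal dwell-time model
#' (seconds), and a Poisson arrival weight.
#'
#' `default_signal_models()` returns the models used throughout: DA and 5-HT
#' amplitudes 15 +/- 7 pA, NE 14 +/- 7 pA, fluctuation scales ordered
#' 5-HT > DA > NE, and dwell parameters giving a median dwell of 10 ms.
#'
#' @param class Class label (one of [nanosig_labels()]).
#' @param amplitude_mean,amplitude_sd Mean and sd of the per-pulse mean
#'   amplitude in pA (Gaussian truncated at 0).
#' @param fluctuation_scale Relative sd of intra-pulse segment levels.
#' @param dwell_meanlog,dwell_sdlog Log-normal dwell-time parameters
#'   (log-seconds).
#' @param weight Mixing weight for Poisson pulse arrivals.
#' @return A one-row (or, for `default_signal_models()`, three-row) tibble.
#' @examples
#' default_signal_models()
#' @export
signal_model <- function(class, amplitude_mean, amplitude_sd,
                         fluctuation_scale,
                         dwell_meanlog = log(0.010), dwell_sdlog = 0.5,
                         weight = 1) {
  stopifnot(class %in% NANOSIG_LABELS, amplitude_mean > 0,
    amplitude_sd >= 0, fluctuation_scale >= 0, weight >= 0)
  tibble(
    class = class, amplitude_mean = amplitude_mean,
    amplitude_sd = amplitude_sd, fluctuation_scale = fluctuation_scale,
    dwell_meanlog = dwell_meanlog, dwell_sdlog = dwell_sdlog, weight = weight
  )
}

#' @rdname signal_model
#' @export
default_signal_models <- function() {
  bind_rows(
    signal_model("DA", 15, 7, fluctuation_scale = 0.25, weight = 1 / 3),
    signal_model("NE", 14, 7, fluctuation_scale = 0.05, weight = 1 / 3),
    signal_model("5HT", 15, 7, fluctuation_scale = 0.55, weight = 1 / 3)
  )
}

#' Simulation configuration
#'
#' Bundles everything the trace simulator needs: measurement duration and
#' sampling rate, junction geometry (gap width, bias) which sets the
#' tunnelling baseline, instrument noise, class signal models with mixing
#' weights, an electrode-migration artifact model, and a seed that fixes all
#' randomness.
#'
#' @param duration Measurement duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param bias_voltage Bias in volts.
#' @param gap_width_nm Electrode gap in nm; sets the tunnelling baseline via
#'   [tunnelling_current()].
#' @param baseline_noise_sd Gaussian instrument noise sd in pA.
#' @param pulse_rate Total molecular pulse arrival rate, events/s, split
#'   across classes by the model weights.
#' @param artifact_rate Electrode-migration spike rate, events/s.
#' @param artifact_amplitude_mean,artifact_amplitude_sd Spike amplitude
#'   distribution in pA (much larger than molecular signals).
#' @param seed Integer seed fixing all randomness.
#' @param models Signal-model tibble (see [signal_model()]); weights must sum
#'   to 1.
#' @param decay_per_nm,contact_conductance Tunnelling decay constant (1/nm)
#'   and contact conductance (S) for the baseline model.
#' @return A `nanosig_sim_config` list.
#' @export
sim_config <- function(duration = 10, sampling_rate = 1e4, bias_voltage = 0.1,
                       gap_width_nm = 0.56, baseline_noise_sd = 1,
                       pulse_rate = 3, artifact_rate = 0.2,
                       artifact_amplitude_mean = 150,
                       artifact_amplitude_sd = 30,
                       seed = 1L, models = default_signal_models(),
                       decay_per_nm = 10.9,
                       contact_conductance = 7.748e-5) {
  stopifnot(duration > 0, sampling_rate > 0, nrow(models) >= 1)
  if (nrow(models) && abs(sum(models$weight) - 1) > 1e-6) {
    stop_nanosig("signal-model mixing weights must sum to 1",
      "nanosig_config_error")
  }
  structure(
    list(
      duration = duration, sampling_rate = sampling_rate,
      bias_voltage = bias_voltage, gap_width_nm = gap_width_nm,
      baseline_noise_sd = baseline_noise_sd, pulse_rate = pulse_rate,
      artifact_rate = artifact_rate,
      artifact_amplitude_mean = artifact_amplitude_mean,
      artifact_amplitude_sd = artifact_amplitude_sd,
      seed = as.integer(seed), models = models,
      decay_per_nm = decay_per_nm, contact_conductance = contact_conductance
    ),
    class = "nanosig_sim_config"
  )
}

#' Tunnelling current across a nanogap
#'
#' Exponential barrier model `I = G_contact * V * exp(-beta * d)`, returned
#' in pA. The inverse is [gap_distance_from_baseline()].
#'
#' @param gap_width_nm Gap distance in nm.
#' @param bias_voltage Bias in volts.
#' @param decay_per_nm Decay constant beta in 1/nm.
#' @param contact_conductance Contact conductance in siemens (default the
#'   conductance quantum G0 = 77.48 uS).
#' @return Current in pA.
#' @export
tunnelling_current <- function(gap_width_nm, bias_voltage = 0.1,
                               decay_per_nm = 10.9,
                               contact_conductance = 7.748e-5) {
  contact_conductance * bias_voltage * exp(-decay_per_nm * gap_width_nm) * 1e12
}

# Gaussian truncated below at 0, by inverse-CDF sampling.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  a <- pnorm(0, mean, sd)
  qnorm(runif(n, a, 1), mean, sd)
}

# Split a span of n samples into k contiguous regions; the first (n %% k)
# regions take one extra sample. Returns the region id of each sample.
region_assignment <- function(n, k = 10L) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(seq_len(k), times = sizes)
}

# Piecewise-constant intra-pulse trajectory: ~10 segments whose levels
# jitter multiplicatively (log-normally) around the pulse amplitude with
# log-sd = fluctuation_scale. Log-normal jitter keeps every segment
# strictly positive, so one molecular residence never splits into several
# apparent pulses, and matches the multiplicative character of junction
# conductance fluctuations.
pulse_trajectory <- function(n_samples, amplitude, fluctuation_scale) {
  k <- min(10L, n_samples)
  seg <- region_assignment(n_samples, k)
  levels <- amplitude * segment_jitter(k, fluctuation_scale)
  levels[seg]
}

# Mean-one multiplicative segment jitter.
segment_jitter <- function(k, fluctuation_scale) {
  exp(fluctuation_scale * rnorm(k) - fluctuation_scale^2 / 2)
}

#' Simulate a nanogap current-time trace with ground truth
#'
#' Generates `baseline + noise + pulses + artifacts`: a constant tunnelling
#' baseline set by gap width and bias, Gaussian instrument noise, Poisson
#' pulse arrivals per class (amplitudes truncated-Gaussian, log-normal
#' dwells, piecewise-constant intra-pulse jitter scaled by the class
#' fluctuation scale), and sporadic high-amplitude electrode-migration
#' spikes. Overlapping pulse spans are merged in the ground truth and
#' flagged. The same seed always yields the identical trace.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (a [current_trace()]) and `truth`
#'   (list with tibbles `pulses` and `artifacts` using half-open sample
#'   spans, the pre-merge event count `n_pulse_events`, and
#'   `low_event_warning`).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "nanosig_sim_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- as.integer(round(config$duration * fs))
    base_pA <- tunnelling_current(config$gap_width_nm, config$bias_voltage,
      config$decay_per_nm, config$contact_conductance)
    current <- rep(base_pA, n)
    if (config$baseline_noise_sd > 0) {
      current <- current + rnorm(n, 0, config$baseline_noise_sd)
    }

    pulses <- pmap(config$models, function(class, amplitude_mean, amplitude_sd,
                                           fluctuation_scale, dwell_meanlog,
                                           dwell_sdlog, weight) {
      rate <- config$pulse_rate * weight
      n_p <- rpois(1, rate * config$duration)
      if (n_p == 0) return(NULL)
      onset <- sort(as.integer(floor(runif(n_p, 0, n))))
      dwell <- rlnorm(n_p, dwell_meanlog, dwell_sdlog)
      len <- pmax(1L, as.integer(round(dwell * fs)))
      amp <- rtruncnorm0(n_p, amplitude_mean, amplitude_sd)
      tibble(class = class, onset_sample = onset,
        offset_sample = pmin(onset + len, n), amplitude = amp,
        fluctuation_scale = fluctuation_scale)
    })
    pulses <- list_rbind(purrr::compact(pulses))
    n_pulse_events <- nrow(pulses)

    if (nrow(pulses)) {
      pulses <- arrange(pulses, .data$onset_sample)
      for (i in seq_len(nrow(pulses))) {
        span <- seq(pulses$onset_sample[i] + 1L, pulses$offset_sample[i])
        current[span] <- current[span] + pulse_trajectory(
          length(span), pulses$amplitude[i], pulses$fluctuation_scale[i])
      }
      pulses <- merge_overlapping_pulses(pulses)
    } else {
      pulses <- tibble(class = character(), onset_sample = integer(),
        offset_sample = integer(), amplitude = numeric(), merged = logical())
    }

    n_a <- rpois(1, config$artifact_rate * config$duration)
    if (n_a > 0) {
      a_on <- sort(as.integer(floor(runif(n_a, 0, n))))
      a_len <- pmax(1L, as.integer(round(rlnorm(n_a, log(0.001), 0.5) * fs)))
      a_amp <- pmax(0, rnorm(n_a, config$artifact_amplitude_mean,
        config$artifact_amplitude_sd))
      for (i in seq_len(n_a)) {
        span <- seq(a_on[i] + 1L, min(a_on[i] + a_len[i], n))
        current[span] <- current[span] + a_amp[i]
      }
      artifacts <- tibble(onset_sample = a_on,
        offset_sample = pmin(a_on + a_len, n), amplitude = a_amp)
    } else {
      artifacts <- tibble(onset_sample = integer(), offset_sample = integer(),
        amplitude = numeric())
    }

    expected_events <- (config$pulse_rate + config$artifact_rate) *
      config$duration
    trace <- current_trace(current,
      sampling_rate = fs,
      bias_voltage = config$bias_voltage,
      metadata = list(gap_width_nm = config$gap_width_nm,
        sample_label = "synthetic", seed = config$seed)
    )
    list(trace = trace, truth = list(
      pulses = pulses, artifacts = artifacts,
      n_pulse_events = n_pulse_events,
      low_event_warning = expected_events < 1
    ))
  })
}

# Merge overlapping truth spans (currents superpose in the trace); merged
# records keep the class of the largest-amplitude contributor and are
# flagged.
merge_overlapping_pulses <- function(pulses) {
  pulses <- arrange(pulses, .data$onset_sample)
  out <- list()
  cur <- pulses[1, ]
  cur$merged <- FALSE
  for (i in seq_len(nrow(pulses))[-1]) {
    p <- pulses[i, ]
    if (p$onset_sample < cur$offset_sample) {
      if (p$amplitude > cur$amplitude) {
        cur$class <- p$class
        cur$amplitude <- p$amplitude
      }
      cur$offset_sample <- max(cur$offset_sample, p$offset_sample)
      cur$merged <- TRUE
    } else {
      out[[length(out) + 1]] <- cur
      cur <- p
      cur$merged <- FALSE
    }
  }
  out[[length(out) + 1]] <- cur
  select(list_rbind(out), "class", "onset_sample", "offset_sample",
    "amplitude", "merged")
}

#' Simulate a labeled feature table directly in feature space
#'
#' Shortcut generator for classifier and denoiser tests that bypasses trace
#' simulation and pulse detection: draws per-signal mean amplitudes from each
#' class model, then the ten region currents `I1..I10` as mean-one
#' log-normal multiplicative jitter around that mean with log-sd equal to
#' the class fluctuation scale (the same law the trace simulator applies
#' segment-wise). `overlap_control` interpolates the class geometry between fully
#' separable (`0`: amplitude means pushed far apart, spreads shrunk) and the
#' realistic heavily overlapped regime (`1`: the model parameters as given,
#' under which classes differ mainly in fluctuation structure).
#'
#' @param models Signal-model tibble (see [signal_model()]).
#' @param n_per_class Signals per class.
#' @param overlap_control In `[0, 1]`; 0 = separable, 1 = model-faithful.
#' @param seed Integer seed.
#' @param source_trace_id Provenance string stored on every row.
#' @return A validated feature table (see [validate_feature_table()]).
#' @examples
#' simulate_feature_set(n_per_class = 5, seed = 1)
#' @export
simulate_feature_set <- function(models = default_signal_models(),
                                 n_per_class = 100, overlap_control = 1,
                                 seed = 1L,
                                 source_trace_id = "synthetic") {
  stopifnot(n_per_class >= 1, overlap_control >= 0, overlap_control <= 1)
  oc <- overlap_control
  with_seed(seed, {
    rows <- pmap(mutate(models, .k = row_number()), function(class,
        amplitude_mean, amplitude_sd, fluctuation_scale, dwell_meanlog,
        dwell_sdlog, weight, .k) {
      mean_eff <- amplitude_mean + (1 - oc) * 8 * amplitude_sd * (.k - 1)
      sd_eff <- oc * amplitude_sd + (1 - oc) * 0.5
      m <- rtruncnorm0(n_per_class, mean_eff, sd_eff)
      z <- matrix(rnorm(n_per_class * 10), n_per_class, 10)
      regions <- m * exp(fluctuation_scale * z - fluctuation_scale^2 / 2)
      regions[regions < 0.01] <- 0.01
      colnames(regions) <- feature_current_cols()
      dwell <- rlnorm(n_per_class, dwell_meanlog, dwell_sdlog)
      bind_cols(
        tibble(
          signal_id = sprintf("%s_%04d", class, seq_len(n_per_class)),
          source_trace_id = source_trace_id
        ),
        as_tibble(regions),
        tibble(
          dwell_time_s = dwell,
          fluctuation_factor = apply(regions, 1, function(v) {
            (max(v) - mean(v)) / mean(v)
          }),
          label = class
        )
      )
    })
    validate_feature_table(list_rbind(rows))
  })
}
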