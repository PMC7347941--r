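# Shared generators for noise-like feature populations and small trace
# fixtures. Everything is built in code at test time; no stored data.

# Electrode-migration artifact surrogate: very large amplitude, sub-ms
# dwell, near-rectangular (low fluctuation).
noise_feature_set <- function(n, seed, amplitude_mean = 150) {
  simulate_feature_set(
    models = signal_model("NOISE", amplitude_mean, 30,
      fluctuation_scale = 0.05, dwell_meanlog = log(0.001)),
    n_per_class = n, seed = seed
  )
}

# Biological-matrix contaminant surrogate: amplitudes overlapping the
# signal range but shifted upward, with far larger intra-pulse fluctuation
# and longer dwells — off the analyte manifold without being artifact-like.
contaminant_feature_set <- function(n, seed) {
  simulate_feature_set(
    models = signal_model("UNLABELED", 32, 8,
      fluctuation_scale = 1.2, dwell_meanlog = log(0.05)),
    n_per_class = n, seed = seed
  )
}

# Feature set for a single analyte class drawn from the default models.
single_class_features <- function(class, n, seed) {
  mods <- default_signal_models()
  simulate_feature_set(
    models = dplyr::mutate(mods[mods$class == class, ], weight = 1),
    n_per_class = n, seed = seed
  )
}

# Unlabeled mixture of the three analytes at given weights plus artifacts.
mixture_sample_features <- function(weights, n_signals, n_noise, seed) {
  n_cls <- round(n_signals * weights / sum(weights))
  parts <- lapply(seq_along(weights), function(i) {
    dplyr::mutate(
      single_class_features(names(weights)[i], n_cls[i], seed + i),
      label = "UNLABELED"
    )
  })
  out <- dplyr::bind_rows(c(parts, list(noise_feature_set(n_noise, seed + 99))))
  dplyr::mutate(out,
    label = "UNLABELED",
    signal_id = sprintf("mix_%05d", dplyr::row_number())
  )
}

# A manually built pulse table row (for feature-extraction unit tests).
manual_pulse <- function(samples, baseline = 0, fs = 1e4, id = "p1") {
  tibble::tibble(
    signal_id = id, source_trace_id = "manual",
    start_sample = 0L, end_sample = length(samples),
    baseline_pA = baseline,
    dwell_time_s = length(samples) / fs,
    samples_pA = list(samples)
  )
}

# Write a simulated per-class trace file; returns the path.
write_sim_trace <- function(path, duration, seed, classes = NULL,
                            weights = NULL, pulse_rate = 3,
                            artifact_rate = 0.2) {
  mods <- default_signal_models()
  if (!is.null(classes)) {
    mods <- mods[mods$class %in% classes, ]
    mods$weight <- if (is.null(weights)) 1 / nrow(mods) else weights
  }
  cfg <- sim_config(duration = duration, pulse_rate = pulse_rate,
    artifact_rate = artifact_rate, models = mods, seed = seed)
  write_trace(simulate_trace(cfg)$trace, path)
  path
}
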