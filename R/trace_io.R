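#' Construct a current-time trace
#'
#' A trace is the raw instrument record: current sampled on a uniform time
#' grid across the nanogap under a fixed bias voltage. It is represented as a
#' tibble with columns `time_s` (seconds, 0-based) and `current_pA`
#' (picoamperes) plus attributes `sampling_rate` (Hz), `bias_voltage` (V) and
#' a free-form `metadata` list (gap width, sample label, ...).
#'
#' @param current Numeric vector of currents in pA (finite, length >= 2).
#' @param sampling_rate Sampling rate in Hz.
#' @param time_s Optional explicit time grid; defaults to
#'   `(0:(n-1)) / sampling_rate`. Must be uniform within relative tolerance
#'   `1e-6` of the step.
#' @param bias_voltage Bias voltage in volts (default 0.1 V).
#' @param metadata Named list of free-form metadata.
#' @return A `nanosig_trace` tibble.
#' @examples
#' tr <- current_trace(c(5, 5.1, 4.9), sampling_rate = 10000)
#' trace_sampling_rate(tr)
#' @export
current_trace <- function(current, sampling_rate, time_s = NULL,
                          bias_voltage = 0.1, metadata = list()) {
  if (length(current) < 2) {
    stop_nanosig("a trace needs at least 2 samples", "nanosig_empty_trace")
  }
  if (!all(is.finite(current))) {
    stop_nanosig("trace currents must be finite", "nanosig_invalid_trace")
  }
  n <- length(current)
  if (is.null(time_s)) {
    time_s <- (seq_len(n) - 1) / sampling_rate
  } else {
    check_uniform_grid(time_s, 1 / sampling_rate)
  }
  out <- tibble(time_s = as.numeric(time_s), current_pA = as.numeric(current))
  structure(out,
    class = c("nanosig_trace", class(out)),
    sampling_rate = as.numeric(sampling_rate),
    bias_voltage = as.numeric(bias_voltage),
    metadata = metadata
  )
}

check_uniform_grid <- function(time_s, step, rel_tol = 1e-6) {
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop_nanosig(
      sprintf("time axis not strictly increasing at row %d", i + 1L),
      "nanosig_nonuniform_grid"
    )
  }
  off <- abs(dt - step) / step
  if (any(off > rel_tol)) {
    i <- which(off > rel_tol)[1]
    stop_nanosig(
      sprintf(
        "non-uniform sampling at row %d: step %.6g s, expected %.6g s",
        i + 1L, dt[i], step
      ),
      "nanosig_nonuniform_grid"
    )
  }
  invisible(TRUE)
}

#' @rdname current_trace
#' @param trace A `nanosig_trace`.
#' @export
trace_sampling_rate <- function(trace) attr(trace, "sampling_rate")

#' @rdname current_trace
#' @export
trace_bias_voltage <- function(trace) attr(trace, "bias_voltage")

#' @rdname current_trace
#' @export
trace_metadata <- function(trace) attr(trace, "metadata") %||% list()

#' @export
print.nanosig_trace <- function(x, ...) {
  cat(sprintf(
    "<nanosig_trace> %d samples @ %g Hz (%.4g s), bias %g V\n",
    nrow(x), trace_sampling_rate(x),
    nrow(x) / trace_sampling_rate(x), trace_bias_voltage(x)
  ))
  md <- trace_metadata(x)
  if (length(md)) {
    cat("metadata:", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

# Unit conversion to pA; readers honor a "unit" metadata key.
current_unit_factor <- function(unit) {
  switch(tolower(unit),
    "pa" = 1, "na" = 1e3, "ua" = 1e6, "µa" = 1e6, "a" = 1e12,
    stop_nanosig(sprintf("unknown current unit '%s'", unit), "nanosig_bad_unit")
  )
}

#' Read a current-time trace from a delimited text file
#'
#' The canonical trace format is plain text: `# key: value` metadata header
#' lines followed by two numeric columns (time in seconds, current in pA;
#' tab, comma or whitespace delimited). Recognized metadata keys:
#' `sampling_rate_hz`, `bias_mV` or `bias_voltage_V`, and `unit` (pA/nA/uA;
#' currents are converted to pA). The sampling rate is inferred from the
#' median time step when absent from the header. The reader validates the
#' uniform-grid invariant and never resamples.
#'
#' @param path Path to the trace file.
#' @param format_hint Optional delimiter hint (`"tab"`, `"comma"`,
#'   `"whitespace"`); auto-detected by default.
#' @return A [current_trace()] tibble.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format_hint = NULL) {
  if (!file.exists(path)) {
    stop_nanosig(sprintf("trace file not found: %s", path), "nanosig_io_error")
  }
  lines <- readr::read_lines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_metadata_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  # drop a column-header line if present
  if (length(body) && grepl("^\\s*time", body[1], ignore.case = TRUE)) {
    body <- body[-1]
  }
  if (length(body) < 2) {
    stop_nanosig("trace has fewer than 2 data rows", "nanosig_empty_trace")
  }
  delim <- format_hint %||% if (grepl(",", body[1])) "comma" else "whitespace"
  dat <- if (delim == "comma") {
    readr::read_csv(I(body), col_names = FALSE, show_col_types = FALSE,
      progress = FALSE)
  } else {
    readr::read_table(I(body), col_names = FALSE, show_col_types = FALSE,
      progress = FALSE)
  }
  if (ncol(dat) < 2 || !all(vapply(dat[1:2], is.numeric, logical(1)))) {
    stop_nanosig("expected two numeric columns (time_s, current_pA)",
      "nanosig_parse_error")
  }
  time_s <- dat[[1]]
  current <- dat[[2]]
  if (!is.null(meta$unit)) {
    current <- current * current_unit_factor(meta$unit)
    meta$unit <- NULL
  }
  fs <- if (!is.null(meta$sampling_rate_hz)) {
    as.numeric(meta$sampling_rate_hz)
  } else {
    1 / median(diff(time_s))
  }
  check_uniform_grid(time_s, 1 / fs)
  bias <- if (!is.null(meta$bias_voltage_V)) {
    as.numeric(meta$bias_voltage_V)
  } else if (!is.null(meta$bias_mV)) {
    as.numeric(meta$bias_mV) / 1000
  } else {
    0.1
  }
  keep <- setdiff(names(meta), c("sampling_rate_hz", "bias_voltage_V", "bias_mV",
    "format"))
  current_trace(current,
    sampling_rate = fs, time_s = time_s, bias_voltage = bias,
    metadata = meta[keep]
  )
}

parse_metadata_lines <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), keys)
}

#' Write a trace to the canonical text format
#'
#' Deterministic layout — a fixed-order metadata header then
#' `time_s<TAB>current_pA` rows with fixed numeric formatting — so repeated
#' writes of the same trace are byte-identical.
#'
#' @param trace A [current_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nanosig_trace"))
  md <- trace_metadata(trace)
  header <- c(
    "# format: nanosig_trace_v1",
    sprintf("# sampling_rate_hz: %.10g", trace_sampling_rate(trace)),
    sprintf("# bias_voltage_V: %.10g", trace_bias_voltage(trace))
  )
  if (length(md)) {
    md <- md[order(names(md))]
    header <- c(header, sprintf("# %s: %s", names(md), as.character(unlist(md))))
  }
  rows <- sprintf("%.10f\t%.6f", trace$time_s, trace$current_pA)
  out <- tryCatch(
    readr::write_lines(c(header, "time_s\tcurrent_pA", rows), path),
    error = function(e) stop_nanosig(
      sprintf("cannot write trace to %s: %s", path, conditionMessage(e)),
      "nanosig_io_error"
    )
  )
  invisible(path)
}

feature_table_cols <- function() {
  c("signal_id", "source_trace_id", feature_current_cols(),
    "dwell_time_s", "fluctuation_factor", "label")
}

#' Validate a feature table
#'
#' A feature table holds one row per pulse signal: the ten region-average
#' currents `I1..I10` (pA), the dwell time (s), the fluctuation factor, and a
#' label from the closed vocabulary [nanosig_labels()].
#'
#' @param table A data frame.
#' @return The table as a validated tibble.
#' @export
validate_feature_table <- function(table) {
  table <- as_tibble(table)
  missing <- setdiff(feature_table_cols(), names(table))
  if (length(missing)) {
    stop_nanosig(
      sprintf("feature table missing columns: %s", paste(missing, collapse = ", ")),
      "nanosig_schema_error"
    )
  }
  bad <- setdiff(unique(table$label), NANOSIG_LABELS)
  if (length(bad)) {
    stop_nanosig(
      sprintf(
        "unknown labels: %s (allowed: %s)",
        paste(bad, collapse = ", "), paste(NANOSIG_LABELS, collapse = ", ")
      ),
      "nanosig_label_error"
    )
  }
  if (nrow(table) && any(table$dwell_time_s <= 0)) {
    stop_nanosig("dwell_time_s must be positive", "nanosig_schema_error")
  }
  table
}

#' Read / write feature tables as CSV
#'
#' CSV with the fixed header
#' `signal_id,source_trace_id,I1,...,I10,dwell_time_s,fluctuation_factor,label`.
#' Rows with labels outside the closed vocabulary are rejected.
#'
#' @param path CSV path.
#' @return `read_feature_table()` returns a validated tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop_nanosig(sprintf("feature table not found: %s", path), "nanosig_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      signal_id = readr::col_character(),
      source_trace_id = readr::col_character(),
      label = readr::col_character(),
      .default = readr::col_double()
    ))
  validate_feature_table(tab)
}

#' @rdname read_feature_table
#' @param table A feature table.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  readr::write_csv(table[, feature_table_cols()], path)
  invisible(path)
}
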