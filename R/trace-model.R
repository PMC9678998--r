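#' Uniformly sampled signal trace
#'
#' Container for a voltage-clamp current sweep (pA) or a fluorescence signal
#' (a.u.) sampled on a uniform time grid. Inward currents recorded at -70 mV
#' are negative; "amplitude" throughout the package means the positive
#' magnitude |peak - baseline|.
#'
#' @param samples Numeric vector of samples (pA or a.u.). Must be finite and
#'   of length >= 2.
#' @param dt Sampling interval in seconds per sample (> 0).
#' @param t0 Time of the first sample in seconds (sweep clock).
#' @param label Free-text label (cell/sweep id).
#' @param units Unit string, `"pA"` for currents, `"au"` for fluorescence.
#' @return An object of class `"Trace"`: a list with fields `samples`, `dt`,
#'   `t0`, `label`, `units`.
#' @examples
#' tr <- trace(c(0, -5, 0), dt = 1e-4)
#' trace_times(tr)
#' @export
trace <- function(samples, dt, t0 = 0, label = "", units = "pA") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("Trace requires at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("Trace samples must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds/sample)", call. = FALSE)
  structure(
    list(samples = samples, dt = as.numeric(dt), t0 = as.numeric(t0),
         label = as.character(label), units = as.character(units)),
    class = "Trace"
  )
}

#' Sample times of a Trace
#'
#' @param x A [trace()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "Trace"))
  x$t0 + (seq_along(x$samples) - 1L) * x$dt
}

#' @export
print.Trace <- function(x, ...) {
  cat(sprintf("<Trace '%s'> %d samples @ %.6g s/sample (%.4g s), units %s\n",
              x$label, length(x$samples), x$dt,
              length(x$samples) * x$dt, x$units))
  invisible(x)
}

#' @export
length.Trace <- function(x) length(x$samples)

#' Stimulation protocol
#'
#' Ordered stimulus times plus train metadata. Covers the protocols used
#' throughout: 40 Hz tetanic trains of 2-2.5 s for cumulative-amplitude
#' analysis, 30 s trains at 10-20 Hz for depression, 0.1 Hz probing for
#' recovery, and paired pulses at 20-1000 ms intervals.
#'
#' @param stim_times Strictly increasing stimulus times in seconds.
#' @param train_freq Within-train stimulation frequency in Hz.
#' @param train_duration Train duration in seconds.
#' @param probe_freq Post-train probe frequency in Hz (e.g. 0.1), or `NA`.
#' @param labels Optional per-stimulus labels (recycled if scalar).
#' @return An object of class `"StimulusProtocol"`.
#' @export
stimulus_protocol <- function(stim_times, train_freq,
                              train_duration = NA_real_,
                              probe_freq = NA_real_, labels = NULL) {
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) < 1L)
    stop("at least one stimulus time required", call. = FALSE)
  if (any(!is.finite(stim_times)) || is.unsorted(stim_times, strictly = TRUE))
    stop("stim_times must be finite and strictly increasing", call. = FALSE)
  if (!is.finite(train_freq) || train_freq <= 0)
    stop("train_freq must be > 0", call. = FALSE)
  if (!is.null(labels)) {
    labels <- rep_len(as.character(labels), length(stim_times))
  }
  structure(
    list(stim_times = stim_times, train_freq = as.numeric(train_freq),
         train_duration = as.numeric(train_duration),
         probe_freq = as.numeric(probe_freq), labels = labels),
    class = "StimulusProtocol"
  )
}

#' Regular train protocol constructor
#'
#' Convenience builder for an n-stimulus train at a fixed frequency starting
#' at `t_start`, optionally followed by post-train probes at `probe_freq`.
#'
#' @param freq Train frequency in Hz.
#' @param duration Train duration in s; the train has `round(freq * duration)`
#'   stimuli at times `t_start + k/freq`, k = 0, 1, ...
#' @param t_start Time of the first stimulus (s).
#' @param probe_freq,probe_duration Optional post-train probing (Hz, s); the
#'   first probe falls one probe interval after the last train stimulus.
#' @return A [stimulus_protocol()].
#' @examples
#' p <- train_protocol(40, 2)        # 80 stimuli, 0 ... 1.975 s
#' length(p$stim_times)
#' @export
train_protocol <- function(freq, duration, t_start = 0,
                           probe_freq = NA_real_, probe_duration = 0) {
  n <- round(freq * duration)
  times <- t_start + (seq_len(n) - 1L) / freq
  if (is.finite(probe_freq) && probe_duration > 0) {
    np <- floor(probe_duration * probe_freq)
    probes <- times[n] + seq_len(np) / probe_freq
    times <- c(times, probes)
  }
  stimulus_protocol(times, train_freq = freq, train_duration = duration,
                    probe_freq = probe_freq)
}

#' @export
print.StimulusProtocol <- function(x, ...) {
  cat(sprintf("<StimulusProtocol> %d stimuli, train %.3g Hz x %.3g s, probe %.3g Hz\n",
              length(x$stim_times), x$train_freq, x$train_duration,
              x$probe_freq))
  invisible(x)
}

#' Fluorescence ROI time series
#'
#' One region of interest's fluorescence over time, with its local background
#' (scalar or per-frame). Channels: `"340"`/`"380"` for Fura-2 excitation
#' pairs, `"green"` for GCaMP/pHluorin.
#'
#' @param frame_times Increasing frame times in seconds.
#' @param F Fluorescence values (a.u.), finite.
#' @param F_background Background fluorescence, scalar or one value per frame,
#'   all >= 0.
#' @param roi_id Identifier string.
#' @param channel One of `"340"`, `"380"`, `"green"`.
#' @return An object of class `"ROISeries"`.
#' @export
roi_series <- function(frame_times, F, F_background = 0,
                       roi_id = "roi", channel = c("green", "340", "380")) {
  channel <- match.arg(channel)
  frame_times <- as.numeric(frame_times)
  F <- as.numeric(F)
  if (length(frame_times) != length(F))
    stop("frame_times and F must have equal length", call. = FALSE)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(F)))
    stop("F must be finite", call. = FALSE)
  F_background <- as.numeric(F_background)
  if (!(length(F_background) %in% c(1L, length(F))))
    stop("F_background must be scalar or per-frame", call. = FALSE)
  if (any(F_background < 0))
    stop("F_background must be >= 0", call. = FALSE)
  structure(
    list(frame_times = frame_times, F = F, F_background = F_background,
         roi_id = as.character(roi_id), channel = channel),
    class = "ROISeries"
  )
}

#' @export
print.ROISeries <- function(x, ...) {
  cat(sprintf("<ROISeries '%s' ch %s> %d frames over %.3g s\n",
              x$roi_id, x$channel, length(x$F),
              diff(range(x$frame_times))))
  invisible(x)
}

# uniform-sampling check used by the reader; tolerance relative to dt
.check_uniform <- function(t, tol_rel = 1e-6) {
  dts <- diff(t)
  if (any(dts <= 0))
    stop("time column is not strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > tol_rel * dt)
    stop("non-uniform sampling beyond tolerance", call. = FALSE)
  dt
}

#' Read a columnar trace/ROI table
#'
#' Reads a plain-text columnar table (CSV) into a [trace()] or [roi_series()].
#' The canonical layout is one file per sweep/ROI with a header naming the
#' time column and the signal column.
#'
#' @param path File path of a CSV table.
#' @param type `"trace"` (uniform sampling enforced to 1e-6 * dt) or `"roi"`.
#' @param time_col,value_col,background_col Column names.
#' @param units,label,roi_id,channel Metadata forwarded to the constructor.
#' @return A `Trace` or `ROISeries`.
#' @export
read_trace_table <- function(path, type = c("trace", "roi"),
                             time_col = "time_s", value_col = "value",
                             background_col = "background",
                             units = "pA", label = NULL,
                             roi_id = NULL, channel = "green") {
  type <- match.arg(type)
  tab <- utils::read.csv(path, check.names = FALSE)
  for (col in c(time_col, value_col))
    if (!col %in% names(tab))
      stop(sprintf("missing required column '%s' in %s", col, path),
           call. = FALSE)
  t <- as.numeric(tab[[time_col]])
  v <- as.numeric(tab[[value_col]])
  if (anyDuplicated(t) || is.unsorted(t, strictly = TRUE))
    stop("time column must be strictly increasing without duplicates",
         call. = FALSE)
  if (type == "trace") {
    dt <- .check_uniform(t)
    trace(v, dt = dt, t0 = t[1L],
          label = label %||% basename(path), units = units)
  } else {
    bg <- if (background_col %in% names(tab)) as.numeric(tab[[background_col]]) else 0
    roi_series(t, v, F_background = bg,
               roi_id = roi_id %||% basename(path), channel = channel)
  }
}

#' Write a Trace or ROISeries as a columnar table
#'
#' Inverse of [read_trace_table()]; the round trip reproduces samples
#' bit-identically (values are written with full precision).
#'
#' @param x A `Trace` or `ROISeries`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "Trace")) {
    df <- data.frame(time_s = trace_times(x), value = x$samples)
  } else if (inherits(x, "ROISeries")) {
    df <- data.frame(time_s = x$frame_times, value = x$F,
                     background = rep_len(x$F_background, length(x$F)))
  } else stop("unsupported type", call. = FALSE)
  .write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer (17 significant digits survives double round trip)
.write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' FNV-1a hash of a configuration object
#'
#' Deterministic 32-bit FNV-1a hash of the JSON serialization of `x`, used to
#' stamp result sidecars with the configuration that produced them.
#'
#' @param x Any JSON-serializable object.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low byte, kept exact in doubles
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # exact 32-bit modular multiply by the FNV prime: split h into 16-bit halves
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write a result table with a JSON provenance sidecar
#'
#' Writes `results` (a data frame, or a list coercible to one) as CSV plus a
#' `<path>.json` sidecar recording the configuration hash, seed and package
#' version. An empty result set yields a header-only CSV.
#'
#' @param results Data frame of results (may have zero rows).
#' @param path Output CSV path.
#' @param config Configuration list recorded (hashed) in the sidecar.
#' @param seed Integer seed recorded in the sidecar, or `NA`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = list(), seed = NA_integer_) {
  df <- as.data.frame(results)
  .write_csv_full(df, path)
  sidecar <- list(
    config_hash = config_hash(config),
    seed = seed,
    n_rows = nrow(df),
    columns = names(df),
    package = "presynquant",
    version = as.character(utils::packageVersion("presynquant"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
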