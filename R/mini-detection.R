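# Miniature PSC detection: threshold-amplitude + threshold-area peak detector
# on a running-median local baseline, as used on TTX recordings.

# trailing running median over k samples (k forced odd, >= 3)
.trailing_median <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, min(k, length(x) - (1L - length(x) %% 2L)))
  rm <- stats::runmed(x, k, endrule = "median")
  shift <- (k - 1L) %/% 2L
  # trailing[i] = centered median at i - shift (window [i-k+1, i])
  idx <- pmax(seq_along(x) - shift, 1L)
  rm[idx]
}

#' Robust noise SD of a trace
#'
#' Estimates the baseline noise standard deviation from the median absolute
#' deviation of first differences (`mad(diff(x)) / sqrt(2)`), which is
#' insensitive to sparse synaptic events riding on the baseline.
#'
#' @param x A [trace()] or numeric vector.
#' @return Noise SD in the trace's units.
#' @export
noise_sd <- function(x) {
  v <- if (inherits(x, "Trace")) x$samples else as.numeric(x)
  stats::mad(diff(v)) / sqrt(2)
}

#' Detect miniature postsynaptic currents
#'
#' Peak detector with amplitude and area thresholds measured from a local
#' baseline (trailing running median over `baseline_window`). Events are
#' deflections whose peak exceeds `amp_threshold` above baseline and whose
#' integral from onset through decay exceeds `area_threshold`. A new event is
#' only opened after the signal has returned below 50% of the previous peak
#' (refractory rule), so events are non-overlapping at their peaks.
#'
#' Defaults are data-driven: `amp_threshold = 5 *` robust noise SD
#' ([noise_sd()]) and `area_threshold = amp_threshold * 1` pA·ms.
#'
#' @param trace A [trace()]; inward (negative) events are the default.
#' @param amp_threshold Amplitude threshold in pA (> 0), or `NULL` for the
#'   5-sigma default.
#' @param area_threshold Area threshold in pA·ms (> 0), or `NULL` for
#'   `amp_threshold * 1` pA·ms.
#' @param baseline_window Length of the trailing baseline window in s.
#' @param direction `"inward"` (downward deflections) or `"outward"`.
#' @param max_event_dur Maximum integration span per event, s.
#' @param kinetics If `TRUE`, fill rise/decay kinetics via [event_kinetics()].
#' @return Data frame with one row per event: `onset_t`, `peak_t`,
#'   `amplitude` (pA, positive), `area` (pA·ms), `rise_10_90` (ms),
#'   `decay_tau` (ms), `kinetics_ok` (logical). Kinetics are `NA` unless
#'   `kinetics = TRUE`.
#' @export
detect_minis <- function(trace, amp_threshold = NULL, area_threshold = NULL,
                         baseline_window = 0.05,
                         direction = c("inward", "outward"),
                         max_event_dur = 0.1, kinetics = FALSE) {
  stopifnot(inherits(trace, "Trace"))
  direction <- match.arg(direction)
  x <- trace$samples
  dt <- trace$dt
  if (length(x) * dt <= baseline_window)
    stop("trace shorter than baseline_window", call. = FALSE)

  if (is.null(amp_threshold)) amp_threshold <- 5 * noise_sd(trace)
  if (is.null(area_threshold)) area_threshold <- amp_threshold * 1  # pA.ms
  if (amp_threshold <= 0 || area_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)

  k <- round(baseline_window / dt)
  base <- .trailing_median(x, k)
  dev <- if (direction == "inward") base - x else x - base

  above <- dev >= amp_threshold
  if (!any(above)) return(.empty_events())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- which(r$values)
  n <- length(x)
  max_span <- round(max_event_dur / dt)
  # 10%-of-peak extent of a candidate peak
  extent <- function(pk) {
    pdev <- dev[pk]
    i0 <- pk
    lim <- max(1L, pk - max_span)
    while (i0 > lim && dev[i0 - 1L] > 0.1 * pdev) i0 <- i0 - 1L
    i1 <- pk
    lim2 <- min(n, pk + max_span)
    while (i1 < lim2 && dev[i1 + 1L] > 0.1 * pdev) i1 <- i1 + 1L
    c(i0, i1)
  }
  acc <- list()   # each: list(pk, i0, i1)
  for (j in reg) {
    seg <- starts[j]:ends[j]
    pk <- seg[which.max(dev[seg])]
    if (length(acc)) {
      last <- acc[[length(acc)]]
      # same event if the candidate lies inside the previous event's extent
      # or the signal has not returned below 50% of the previous peak
      same <- pk <= last$i1 ||
        min(dev[last$pk:pk]) > 0.5 * dev[last$pk]
      if (same) {
        if (dev[pk] > dev[last$pk]) {
          ex <- extent(pk)
          acc[[length(acc)]] <- list(pk = pk, i0 = min(ex[1L], last$i0),
                                     i1 = max(ex[2L], last$i1))
        } else {
          acc[[length(acc)]]$i1 <- max(last$i1, extent(pk)[2L])
        }
        next
      }
    }
    ex <- extent(pk)
    acc[[length(acc) + 1L]] <- list(pk = pk, i0 = ex[1L], i1 = ex[2L])
  }

  tt <- trace_times(trace)
  rows <- lapply(acc, function(e) {
    area <- sum(dev[e$i0:e$i1]) * dt * 1000  # pA.ms
    c(onset_t = tt[e$i0], peak_t = tt[e$pk], amplitude = dev[e$pk],
      area = area)
  })
  ev <- as.data.frame(do.call(rbind, rows))
  ev <- ev[ev$area >= area_threshold, , drop = FALSE]
  if (nrow(ev) == 0L) return(.empty_events())
  ev$rise_10_90 <- NA_real_
  ev$decay_tau <- NA_real_
  ev$kinetics_ok <- NA
  rownames(ev) <- NULL
  if (kinetics) {
    for (i in seq_len(nrow(ev)))
      ev[i, ] <- event_kinetics(trace, ev[i, ], direction = direction,
                                baseline_window = baseline_window)
  }
  ev
}

.empty_events <- function() {
  data.frame(onset_t = numeric(0), peak_t = numeric(0),
             amplitude = numeric(0), area = numeric(0),
             rise_10_90 = numeric(0), decay_tau = numeric(0),
             kinetics_ok = logical(0))
}

# linear interpolation time of an upward level crossing between samples
.cross_time <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Rise and decay kinetics of one miniature event
#'
#' Fills `rise_10_90` (time from 10% to 90% of peak on the rising phase, ms)
#' and `decay_tau` (single-exponential time constant fitted to the 90-10%
#' decay segment, ms) for a detected event. The local baseline is the median
#' of `baseline_window` preceding the onset. If the decay segment is clipped
#' by the trace end or the exponential fit fails to converge, kinetics are
#' flagged missing (`kinetics_ok = FALSE`) and the event is retained.
#'
#' @param trace The [trace()] the event was detected in.
#' @param event One-row data frame as returned by [detect_minis()].
#' @param direction `"inward"` or `"outward"`.
#' @param baseline_window Baseline window before onset, s.
#' @return The event row with `rise_10_90`, `decay_tau`, `kinetics_ok` set.
#' @export
event_kinetics <- function(trace, event,
                           direction = c("inward", "outward"),
                           baseline_window = 0.05) {
  stopifnot(inherits(trace, "Trace"))
  direction <- match.arg(direction)
  x <- trace$samples
  tt <- trace_times(trace)
  dt <- trace$dt
  pk <- which.min(abs(tt - event$peak_t))
  on <- which.min(abs(tt - event$onset_t))
  if (pk < 1L || pk > length(x))
    stop("event peak outside trace", call. = FALSE)

  b0 <- max(1L, on - round(baseline_window / dt))
  base <- stats::median(x[b0:max(b0, on - 1L)])
  dev <- if (direction == "inward") base - x else x - base
  amp <- dev[pk]

  event$kinetics_ok <- FALSE
  event$rise_10_90 <- NA_real_
  event$decay_tau <- NA_real_
  if (!is.finite(amp) || amp <= 0) return(event)

  # rising phase: walk back from the peak to the last 90% and 10% crossings
  back_lim <- max(1L, pk - round(baseline_window / dt))
  idx <- back_lim:pk
  b90 <- idx[dev[idx] < 0.9 * amp]
  a90 <- if (length(b90)) max(b90) else NA_integer_
  if (!is.na(a90)) {
    b10 <- idx[idx <= a90 & dev[idx] < 0.1 * amp]
    a10 <- if (length(b10)) max(b10) else NA_integer_
    if (!is.na(a10)) {
      t10 <- .cross_time(tt[a10], tt[a10 + 1L], dev[a10], dev[a10 + 1L],
                         0.1 * amp)
      t90 <- .cross_time(tt[a90], tt[a90 + 1L], dev[a90], dev[a90 + 1L],
                         0.9 * amp)
      event$rise_10_90 <- (t90 - t10) * 1000
    }
  }

  # decay segment: from the 90% crossing after the peak down to 10%
  n <- length(x)
  d0 <- pk
  while (d0 < n && dev[d0] > 0.9 * amp) d0 <- d0 + 1L
  d1 <- d0
  while (d1 < n && dev[d1] > 0.1 * amp) d1 <- d1 + 1L
  clipped <- d1 >= n && dev[n] > 0.1 * amp
  if (clipped || d1 - d0 < 4L) return(event)

  ts <- tt[d0:d1] - tt[d0]
  ys <- dev[d0:d1]
  pos <- ys > 0
  if (sum(pos) < 4L) return(event)
  # log-linear start, then Levenberg-Marquardt refinement
  lf <- stats::lm(log(ys[pos]) ~ ts[pos])
  tau0 <- -1 / unname(stats::coef(lf)[2L])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(ts)) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-ts / tau),
                      start = list(A = max(ys), tau = tau0),
                      lower = c(0, dt / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(event)
  event$decay_tau <- stats::coef(fit)[["tau"]] * 1000
  event$kinetics_ok <- TRUE
  event
}

#' Per-cell summary of miniature events
#'
#' @param events Event data frame from [detect_minis()].
#' @param duration Recording duration in seconds (> 0).
#' @return One-row data frame: `frequency` (Hz, = `n_events / duration`
#'   exactly), `mean_amplitude`, `median_amplitude` (pA), `n_events`,
#'   `duration` (s).
#' @export
mini_stats <- function(events, duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  n <- nrow(events)
  data.frame(
    frequency = n / duration,
    mean_amplitude = if (n) mean(events$amplitude) else NA_real_,
    median_amplitude = if (n) stats::median(events$amplitude) else NA_real_,
    n_events = n,
    duration = duration
  )
}

#' Windowed time course of mini frequency and amplitude
#'
#' Splits detected events into consecutive analysis windows (e.g. a 2-min
#' baseline followed by three 5-min windows around a BAPTA-AM application)
#' and reports per-window statistics, normalized to the first window.
#'
#' @param events Event data frame from [detect_minis()].
#' @param windows Two-column matrix or list of `c(t_start, t_end)` pairs in
#'   seconds; must be disjoint and ordered.
#' @return Data frame with one row per window: `t_start`, `t_end`,
#'   `frequency`, `mean_amplitude`, `n_events`, plus `norm_frequency` and
#'   `norm_amplitude` (relative to window 1). If the first window contains no
#'   events the normalized columns are `NA` and a warning is raised.
#' @export
mini_timecourse <- function(events, windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  if (any(windows[, 2L] <= windows[, 1L]))
    stop("each window must have t_end > t_start", call. = FALSE)
  if (nrow(windows) > 1L &&
      any(windows[-1L, 1L] < windows[-nrow(windows), 2L]))
    stop("windows must be disjoint and ordered", call. = FALSE)

  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- events$peak_t >= w[1L] & events$peak_t < w[2L]
    st <- mini_stats(events[sel, , drop = FALSE], duration = w[2L] - w[1L])
    cbind(data.frame(window = i, t_start = w[1L], t_end = w[2L]),
          st[, c("frequency", "mean_amplitude", "n_events")])
  })
  out <- do.call(rbind, rows)
  if (out$n_events[1L] == 0L) {
    warning("first window empty: normalization undefined", call. = FALSE)
    out$norm_frequency <- NA_real_
    out$norm_amplitude <- NA_real_
  } else {
    out$norm_frequency <- out$frequency / out$frequency[1L]
    out$norm_amplitude <- out$mean_amplitude / out$mean_amplitude[1L]
  }
  out
}
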