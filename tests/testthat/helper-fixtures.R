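# Shared fixture builders (all programmatic; no stored data).

# bi-exponential PSC kernel normalized to unit peak
psc_kernel <- function(rise_ms, decay_ms, dt, span = 8) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  tk <- seq(0, span * td, by = dt)
  k <- exp(-tk / td) - exp(-tk / tr)
  k / max(k)
}

# trace with inward bi-exponential events injected at known times
make_mini_trace <- function(event_times, amplitudes, duration,
                            dt = 1e-4, noise_sd = 0, rise_ms = 0.5,
                            decay_ms = 5, seed = 1) {
  n <- round(duration / dt)
  x <- if (noise_sd > 0) {
    set.seed(seed)
    rnorm(n, 0, noise_sd)
  } else numeric(n)
  kern <- psc_kernel(rise_ms, decay_ms, dt)
  for (i in seq_along(event_times)) {
    i0 <- floor(event_times[i] / dt) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] - amplitudes[i] * kern[seq_along(idx)]
  }
  trace(x, dt = dt, units = "pA")
}

# idealized event whose decay segment is exactly single-exponential:
# linear rise over rise_ms, then pure exp decay with decay_ms
make_exact_event_trace <- function(amp = 50, t_on = 0.5, rise_ms = 0.5,
                                   decay_ms = 5, duration = 2, dt = 1e-4) {
  t <- seq(0, duration - dt, by = dt)
  x <- numeric(length(t))
  i_on <- round(t_on / dt) + 1L
  nr <- round(rise_ms / 1000 / dt)
  x[i_on:(i_on + nr)] <- -amp * seq(0, 1, length.out = nr + 1L)
  idec <- (i_on + nr + 1L):length(t)
  x[idec] <- -amp * exp(-(t[idec] - t[i_on + nr]) / (decay_ms / 1000))
  trace(x, dt = dt, units = "pA")
}

# evoked-response table from stimulus times and amplitudes
make_responses <- function(stim_t, amplitude) {
  data.frame(index_in_train = seq_along(stim_t), stim_t = stim_t,
             baseline = 0, peak = -amplitude, amplitude = amplitude)
}

# match detections to ground-truth injection times (onset within window, s)
match_events <- function(detected_onsets, true_times,
                         before = 0.002, after = 0.005) {
  recall_hits <- vapply(true_times, function(tt) {
    any(detected_onsets >= tt - before & detected_onsets <= tt + after)
  }, logical(1L))
  fp <- vapply(detected_onsets, function(o) {
    !any(o >= true_times - before & o <= true_times + 2 * after)
  }, logical(1L))
  list(recall_hits = recall_hits, false_pos = fp)
}
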