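# Evoked-train analysis: amplitude extraction, paired-pulse ratio,
# cumulative-amplitude RRP/Pr back-extrapolation, and depression/recovery
# exponential fits.

#' Measure evoked response amplitudes in a train
#'
#' For each stimulus: baseline = mean of the 2 ms preceding the stimulus;
#' peak = extremal deflection from baseline searched from
#' `stim_t + artifact_blank` to the next stimulus (or `max_window` after the
#' last one); amplitude = |peak - baseline|. The blank skips the brief
#' somatic depolarization artifact.
#'
#' @param trace A [trace()] containing the evoked sweep (pA).
#' @param protocol A [stimulus_protocol()] whose times fall inside the trace.
#' @param artifact_blank Post-stimulus blanking in ms (default 2).
#' @param baseline_ms Pre-stimulus baseline window in ms (default 2).
#' @param max_window Peak-search span after the last stimulus, s.
#' @return Data frame with one row per stimulus: `index_in_train`, `stim_t`,
#'   `baseline`, `peak`, `amplitude` (pA, positive).
#' @export
measure_evoked_amplitudes <- function(trace, protocol, artifact_blank = 2,
                                      baseline_ms = 2, max_window = 0.05) {
  stopifnot(inherits(trace, "Trace"), inherits(protocol, "StimulusProtocol"))
  st <- protocol$stim_times
  tt <- trace_times(trace)
  if (st[1L] < tt[1L] || st[length(st)] > tt[length(tt)])
    stop("stimulus times outside trace", call. = FALSE)
  blank_s <- artifact_blank / 1000
  if (length(st) > 1L && min(diff(st)) <= blank_s)
    stop("inter-stimulus interval shorter than artifact_blank", call. = FALSE)
  dt <- trace$dt
  x <- trace$samples
  n <- length(x)
  nb <- max(1L, round(baseline_ms / 1000 / dt))

  rows <- lapply(seq_along(st), function(k) {
    i_st <- which.min(abs(tt - st[k]))
    b0 <- max(1L, i_st - nb)
    bl <- mean(x[b0:max(b0, i_st - 1L)])
    w0 <- min(n, i_st + max(1L, round(blank_s / dt)))
    w1 <- if (k < length(st)) which.min(abs(tt - st[k + 1L])) - 1L
          else min(n, i_st + round(max_window / dt))
    w1 <- max(w1, w0)
    seg <- x[w0:w1]
    ip <- which.max(abs(seg - bl))
    data.frame(index_in_train = k, stim_t = st[k], baseline = bl,
               peak = seg[ip], amplitude = abs(seg[ip] - bl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired-pulse ratio
#'
#' PPR = I2/I1 for two-stimulus sweeps, aggregated per inter-stimulus
#' interval (ISI) across sweeps. Values > 1 indicate facilitation, < 1
#' depression.
#'
#' @param responses Either a data frame from [measure_evoked_amplitudes()]
#'   with exactly two rows (one sweep), or a list of such data frames
#'   (several sweeps, possibly at different ISIs).
#' @return Data frame with columns `isi_ms`, `ppr` (mean across sweeps),
#'   `n_sweeps`. Sweeps with I1 = 0 are flagged `NA` and excluded from the
#'   mean with a warning.
#' @examples
#' sweep <- data.frame(index_in_train = 1:2, stim_t = c(0, 0.05),
#'                     baseline = 0, peak = -50, amplitude = c(50, 25))
#' compute_ppr(sweep)   # PPR 0.5 at 50 ms
#' @export
compute_ppr <- function(responses) {
  if (is.data.frame(responses)) responses <- list(responses)
  per_sweep <- lapply(responses, function(sw) {
    if (nrow(sw) != 2L)
      stop("each paired-pulse sweep must contain exactly two responses",
           call. = FALSE)
    isi_ms <- (sw$stim_t[2L] - sw$stim_t[1L]) * 1000
    ppr <- if (sw$amplitude[1L] == 0) {
      warning("I1 = 0: PPR undefined for one sweep", call. = FALSE)
      NA_real_
    } else sw$amplitude[2L] / sw$amplitude[1L]
    data.frame(isi_ms = isi_ms, ppr = ppr)
  })
  all <- do.call(rbind, per_sweep)
  sp <- split(all$ppr, all$isi_ms)  # factor levels sort numerically
  out <- data.frame(
    isi_ms = as.numeric(names(sp)),
    ppr = vapply(sp, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), numeric(1L)),
    n_sweeps = vapply(sp, function(v) sum(!is.na(v)), integer(1L)))
  rownames(out) <- NULL
  out[order(out$isi_ms), , drop = FALSE]
}

#' Cumulative amplitude profile of a train
#'
#' Running sum of evoked amplitudes indexed by stimulus time (relative to the
#' first stimulus). The profile of a depressing train rises fast while the
#' RRP empties, then climbs linearly at the replenishment-limited rate.
#'
#' @param responses Data frame from [measure_evoked_amplitudes()] (>= 2 rows).
#' @return Object of class `"CumulativeFit"`: list with `t` (s, 0 at first
#'   stimulus), `cum_amplitudes` (pA), `I1` (pA), and unfilled fit fields
#'   (`slope`, `intercept_RRP`, `Pr`, `r2`, `fit_window`, `valid`).
#' @export
cumulative_profile <- function(responses) {
  if (nrow(responses) < 2L)
    stop("need at least 2 responses", call. = FALSE)
  amps <- responses$amplitude
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(
    list(t = responses$stim_t - responses$stim_t[1L],
         cum_amplitudes = cumsum(amps),
         I1 = amps[1L],
         fit_window = c(NA_real_, NA_real_),
         slope = NA_real_, intercept_RRP = NA_real_,
         r2 = NA_real_, Pr = NA_real_, valid = NA),
    class = "CumulativeFit"
  )
}

#' @export
print.CumulativeFit <- function(x, ...) {
  cat(sprintf("<CumulativeFit> %d stimuli, I1 = %.4g pA\n",
              length(x$t), x$I1))
  if (!is.na(x$intercept_RRP))
    cat(sprintf("  RRP = %.6g pA, Pr = %.4g, slope = %.4g pA/s, r2 = %.4g (window %.3g-%.3g s, valid = %s)\n",
                x$intercept_RRP, x$Pr, x$slope, x$r2,
                x$fit_window[1L], x$fit_window[2L], x$valid))
  invisible(x)
}

#' Estimate RRP and release probability by back-extrapolation
#'
#' Ordinary least-squares regression of the cumulative amplitude against
#' stimulus time over the linear late phase of the train (default 0.5-1 s,
#' i.e. stimuli 21-40 of a 40 Hz train), retrogradely extrapolated to the
#' time of the first stimulus (t = 0). The y-intercept estimates the
#' readily releasable pool of synchronous release (`intercept_RRP`, pA) and
#' `Pr = I1 / intercept_RRP`. The method assumes release probability
#' approaches unity during the train and a constant vesicle replenishment
#' limiting the steady state; under that model the intercept equals
#' `N q - c (1 - Pr) / Pr` quanta (c = sites replenished per interval), so
#' for Pr < 1 it underestimates the pool by a margin that shrinks
#' monotonically as Pr approaches 1.
#'
#' @param cum A [cumulative_profile()] object.
#' @param fit_window Half-open window `[t1, t2)` in seconds, relative to the
#'   first stimulus, over which the profile is regressed (default
#'   `c(0.5, 1.0)`).
#' @return The `CumulativeFit` with `slope` (pA/s), `intercept_RRP` (pA),
#'   `r2`, `Pr` and `valid` filled. `valid` is `FALSE` when the intercept is
#'   <= 0, Pr > 1, or the train shows no depression (late amplitudes are
#'   >= 90% of I1, so no replenishment-limited steady state was reached and
#'   the back-extrapolation is meaningless).
#' @export
estimate_rrp_pr <- function(cum, fit_window = c(0.5, 1.0)) {
  stopifnot(inherits(cum, "CumulativeFit"))
  sel <- cum$t >= fit_window[1L] & cum$t < fit_window[2L]
  if (sum(sel) < 3L)
    stop("fewer than 3 stimuli in fit window", call. = FALSE)
  fit <- stats::lm(y ~ t, data = data.frame(t = cum$t[sel],
                                            y = cum$cum_amplitudes[sel]))
  co <- stats::coef(fit)
  cum$fit_window <- as.numeric(fit_window)
  cum$intercept_RRP <- unname(co[1L])
  cum$slope <- unname(co[2L])
  cum$r2 <- suppressWarnings(summary(fit)$r.squared)
  cum$Pr <- if (cum$intercept_RRP > 0) cum$I1 / cum$intercept_RRP else NA_real_
  amps <- c(cum$cum_amplitudes[1L], diff(cum$cum_amplitudes))
  depressing <- cum$I1 > 0 && mean(amps[sel]) < 0.9 * cum$I1
  cum$valid <- isTRUE(cum$intercept_RRP > 0 && !is.na(cum$Pr) &&
                      cum$Pr <= 1 + 1e-9 && depressing)
  cum
}

# deterministic exponential-fit seeding: SSC from the tail, tau from a
# log-linear pre-fit of (y - SSC) clamped positive
.tail_level <- function(y, frac = 0.1) {
  n <- length(y)
  mean(y[max(1L, n - max(1L, round(frac * n)) + 1L):n])
}

.loglin_tau <- function(t, r, fallback) {
  ok <- r > 0 & is.finite(r)
  if (sum(ok) < 3L) return(fallback)
  co <- stats::coef(stats::lm(log(r[ok]) ~ t[ok]))
  tau <- -1 / co[2L]
  if (!is.finite(tau) || tau <= 0) fallback else unname(tau)
}

#' Fit the depression time course of a train
#'
#' Normalizes the amplitudes to the first response and fits
#' `y(t) = SSC + A_fast exp(-t/tau_fast) + A_slow exp(-t/tau_slow)`
#' by bounded Levenberg-Marquardt least squares (all parameters >= 0), with
#' `tau_fast < tau_slow` enforced by post-fit ordering. The steady-state
#' current (SSC) is reported as a fraction of I1 (and in pA alongside). If
#' the bi-exponential does not converge, or a mono-exponential achieves a
#' lower AIC, the mono-exponential `y(t) = SSC + A exp(-t/tau)` is reported
#' with `model = "mono"` and the slow component set to `NA`.
#'
#' @param responses Data frame from [measure_evoked_amplitudes()] with at
#'   least 20 rows (e.g. 30 s at 20 Hz = 600 stimuli).
#' @return One-row data frame: `SSC` (fraction of I1), `SSC_pA`, `A_fast`,
#'   `tau_fast` (s), `A_slow`, `tau_slow` (s), `model` ("bi" or "mono"),
#'   `converged`.
#' @export
fit_depression <- function(responses) {
  if (nrow(responses) < 20L)
    stop("need at least 20 train responses", call. = FALSE)
  I1 <- responses$amplitude[1L]
  if (I1 <= 0) stop("I1 must be > 0 to normalize", call. = FALSE)
  t <- responses$stim_t - responses$stim_t[1L]
  y <- responses$amplitude / I1

  # flat trains carry no kinetic information: report the level directly
  if (stats::sd(y) < 1e-10 * max(abs(y), 1))
    return(data.frame(SSC = mean(y), SSC_pA = mean(y) * I1,
                      A_fast = 0, tau_fast = NA_real_,
                      A_slow = NA_real_, tau_slow = NA_real_,
                      model = "mono", converged = TRUE))

  ssc0 <- .tail_level(y)
  r <- y - ssc0
  tau_s0 <- .loglin_tau(t[t > max(t) / 3], r[t > max(t) / 3], max(t) / 4)
  tau_f0 <- .loglin_tau(t[t <= max(t) / 10], r[t <= max(t) / 10], tau_s0 / 10)
  if (tau_f0 >= tau_s0) tau_f0 <- tau_s0 / 10
  a0 <- max(y[1L] - ssc0, 1e-3)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  # a few deterministic start sets guard against local minima of the
  # bi-exponential surface (depression can be as fast as a single
  # inter-stimulus interval); the best converged fit (by RSS) is kept
  Tmax <- max(t)
  isi <- stats::median(diff(t))
  tau_starts <- list(c(tau_f0, tau_s0),
                     c(Tmax / 100, Tmax / 6),
                     c(Tmax / 400, Tmax / 30),
                     c(isi, 10 * isi))
  keep_best <- function(best, cand) {
    if (!is.null(cand) &&
        (is.null(best) || stats::deviance(cand) < stats::deviance(best)))
      cand else best
  }
  bi <- NULL
  for (ts0 in tau_starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ ssc + af * exp(-t / tf) + as * exp(-t / ts),
        start = list(ssc = max(ssc0, 1e-6), af = a0 * 0.6, as = a0 * 0.4,
                     tf = ts0[1L], ts = ts0[2L]),
        lower = c(0, 0, 0, 1e-6, 1e-6), control = ctrl),
      error = function(e) NULL)
    bi <- keep_best(bi, cand)
  }
  mono <- NULL
  for (tau0 in c(tau_s0, Tmax / 20, 2 * isi)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ ssc + a * exp(-t / tau),
        start = list(ssc = max(ssc0, 1e-6), a = a0, tau = tau0),
        lower = c(0, 0, 1e-6), control = ctrl),
      error = function(e) NULL)
    mono <- keep_best(mono, cand)
  }
  if (is.null(bi) && is.null(mono))
    stop("depression fit failed to converge", call. = FALSE)

  use_bi <- !is.null(bi) && (is.null(mono) ||
                             stats::AIC(bi) < stats::AIC(mono))
  if (use_bi) {
    co <- stats::coef(bi)
    tf <- co[["tf"]]; ts <- co[["ts"]]
    af <- co[["af"]]; as_ <- co[["as"]]
    if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                   tmp <- af; af <- as_; as_ <- tmp }
    data.frame(SSC = co[["ssc"]], SSC_pA = co[["ssc"]] * I1,
               A_fast = af, tau_fast = tf, A_slow = as_, tau_slow = ts,
               model = "bi", converged = TRUE)
  } else {
    co <- stats::coef(mono)
    data.frame(SSC = co[["ssc"]], SSC_pA = co[["ssc"]] * I1,
               A_fast = co[["a"]], tau_fast = co[["tau"]],
               A_slow = NA_real_, tau_slow = NA_real_,
               model = "mono", converged = TRUE)
  }
}

#' Fit recovery from depression
#'
#' After a depressing train the stimulation returns to a low probe frequency
#' (typically 0.1 Hz) and the response climbs back toward its pre-train
#' level. Fits the mono-exponential rise
#' `y(t) = SSC - (SSC - y0) exp(-t/tau)` to probe amplitudes normalized to
#' the pre-train first response, with t = 0 at the first probe.
#'
#' @param post_responses Data frame from [measure_evoked_amplitudes()] for
#'   the post-train probes (>= 4 rows).
#' @param I1_pre Pre-train first-response amplitude in pA (> 0) used for
#'   normalization.
#' @return One-row data frame: `SSC` (fraction of pre-train I1, the recovery
#'   plateau), `tau` (s), `first_post_response` (fitted y at t = 0),
#'   `converged`.
#' @export
fit_recovery <- function(post_responses, I1_pre) {
  if (nrow(post_responses) < 4L)
    stop("need at least 4 probe responses", call. = FALSE)
  if (!is.finite(I1_pre) || I1_pre <= 0)
    stop("I1_pre must be > 0", call. = FALSE)
  t <- post_responses$stim_t - post_responses$stim_t[1L]
  y <- post_responses$amplitude / I1_pre

  ssc0 <- .tail_level(y, 0.25)
  y00 <- y[1L]
  tau0 <- .loglin_tau(t, ssc0 - y, max(t) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ssc - (ssc - y0) * exp(-t / tau),
      start = list(ssc = max(ssc0, 1e-6), y0 = max(y00, 0), tau = tau0),
      lower = c(0, 0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # flat series: plateau equals the mean, no identifiable time constant
    if (stats::sd(y) < 1e-12 * max(abs(y), 1))
      return(data.frame(SSC = mean(y), tau = NA_real_,
                        first_post_response = y[1L], converged = FALSE))
    stop("recovery fit failed to converge", call. = FALSE)
  }
  co <- stats::coef(fit)
  data.frame(SSC = co[["ssc"]], tau = co[["tau"]],
             first_post_response = co[["y0"]], converged = TRUE)
}
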