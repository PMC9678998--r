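# synaptopHluorin (sypHy) analysis: dF/F0, endocytosis time constant,
# Fmax normalization and train-recovery ratio.

#' Background-subtracted dF/F0 of a pHluorin ROI
#'
#' `F0` is the mean of the baseline window (default the first 5 s before the
#' stimulus) after background subtraction; the series is
#' `(F(t) - F0) / F0`. The peak dF/F0 after a 20 AP @ 100 Hz burst is the
#' imaging readout of the releasable pool.
#'
#' @param roi An [roi_series()] (channel `"green"`).
#' @param baseline_window Length of the pre-stimulus baseline in s (default 5);
#'   the window starts at the first frame.
#' @param background Optional scalar/per-frame background overriding the
#'   ROI's own `F_background`.
#' @return List with `t` (s), `dff` (unitless series), `F0` (a.u.),
#'   class `"DFFSeries"`.
#' @export
dff <- function(roi, baseline_window = 5, background = NULL) {
  stopifnot(inherits(roi, "ROISeries"))
  bg <- background %||% roi$F_background
  Fc <- roi$F - rep_len(as.numeric(bg), length(roi$F))
  t <- roi$frame_times
  sel <- t < t[1L] + baseline_window
  if (sum(sel) < 2L)
    stop("need >= 2 frames in the baseline window", call. = FALSE)
  F0 <- mean(Fc[sel])
  if (F0 <= 0)
    stop("F0 <= 0 after background subtraction", call. = FALSE)
  structure(list(t = t, dff = (Fc - F0) / F0, F0 = F0),
            class = "DFFSeries")
}

#' @export
print.DFFSeries <- function(x, ...) {
  cat(sprintf("<DFFSeries> %d frames, F0 = %.4g a.u., peak dF/F0 = %.4g\n",
              length(x$t), x$F0, max(x$dff)))
  invisible(x)
}

#' Fit the endocytosis time constant
#'
#' Fits the post-stimulus fluorescence decay with the single-exponential
#' `dF/F0(t) = plateau + amp * exp(-t / tau)` (t = 0 at the post-stimulus
#' peak), by bounded Levenberg-Marquardt least squares. `tau` is the
#' endocytosis/re-acidification time constant; `plateau` is the residual
#' (surface-stranded) dF/F0. An increasing segment, or one with no
#' resolvable decay amplitude, is flagged invalid.
#'
#' @param x A `"DFFSeries"` from [dff()], or a list with `t` and `dff`.
#' @param post_stim_window `c(t_start, t_end)` in s bounding the decay
#'   segment; the fit starts at the maximum within it (default: from the
#'   global peak to the last frame).
#' @return One-row data frame: `tau_endo` (s), `plateau_dff`, `peak_dff`,
#'   `valid`.
#' @export
fit_endocytosis <- function(x, post_stim_window = NULL) {
  t <- x$t; y <- x$dff
  if (is.null(post_stim_window))
    post_stim_window <- range(t)  # fit starts at the maximum inside it
  sel <- t >= post_stim_window[1L] & t <= post_stim_window[2L]
  if (sum(sel) < 4L) stop("fewer than 4 frames in decay window", call. = FALSE)
  ts <- t[sel]; ys <- y[sel]
  ip <- which.max(ys)
  ts <- ts[ip:length(ts)] - ts[ip]
  ys <- ys[ip:length(ys)]
  peak <- ys[1L]
  out <- data.frame(tau_endo = NA_real_, plateau_dff = NA_real_,
                    peak_dff = peak, valid = FALSE)
  # peak at (or near) the window end: nothing decays after it
  if (length(ys) < 4L) return(out)
  slope <- stats::coef(stats::lm(ys ~ ts))[2L]
  if (slope >= 0) return(out)                      # not decaying
  pl0 <- .tail_level(ys, 0.2)
  amp0 <- peak - pl0
  if (amp0 <= max(1e-12, 1e-3 * max(abs(ys)))) return(out)  # no decay amplitude
  tau0 <- .loglin_tau(ts, ys - pl0, max(ts) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ pl + a * exp(-ts / tau),
                      start = list(pl = max(pl0, 0), a = amp0, tau = tau0),
                      lower = c(0, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  co <- stats::coef(fit)
  data.frame(tau_endo = co[["tau"]], plateau_dff = co[["pl"]],
             peak_dff = peak, valid = TRUE)
}

#' Recovery ratio of releasable-pool probes around a conditioning train
#'
#' In the standard protocol three 20 AP @ 100 Hz probe responses are
#' collected before (train 1) and one or more after (train 2) a long
#' conditioning stimulation (600 AP @ 20 Hz); all peaks are normalized to
#' the first probe. The recovery ratio is
#' `mean(train2_peaks) / mean(train1_peaks)` and is invariant to any common
#' normalization of both trains.
#'
#' @param train1_peaks Normalized peak dF/F0 of the pre-conditioning probes
#'   (typically length 3).
#' @param train2_peaks Normalized peak(s) after the conditioning train.
#' @return Unitless recovery ratio.
#' @export
rrp_recovery_ratio <- function(train1_peaks, train2_peaks) {
  train1_peaks <- as.numeric(train1_peaks)
  train2_peaks <- as.numeric(train2_peaks)
  if (length(train1_peaks) == 0L || length(train2_peaks) == 0L)
    stop("both probe sets must be non-empty", call. = FALSE)
  m1 <- mean(train1_peaks)
  if (m1 == 0) stop("train-1 mean is zero", call. = FALSE)
  mean(train2_peaks) / m1
}

#' Normalize a pHluorin trace to the NH4Cl maximum
#'
#' Perfusion with 50 mM NH4Cl alkalinizes all vesicles and reveals the total
#' fluorescence `Fmax` at responsive terminals. The trace (background
#' subtracted) is divided by the mean fluorescence over the NH4Cl window,
#' yielding values in [0, ~1] where the baseline equals the surface
#' (non-quenched) fraction of the reporter.
#'
#' @param roi An [roi_series()].
#' @param nh4cl_window `c(t_start, t_end)` of the NH4Cl perfusion, s.
#' @param baseline_window Baseline length (s) used to check alkalinization.
#' @return List with `t`, `F_norm` (unitless series) and `Fmax` (a.u.).
#' @export
normalize_to_fmax <- function(roi, nh4cl_window, baseline_window = 5) {
  stopifnot(inherits(roi, "ROISeries"))
  Fc <- roi$F - rep_len(as.numeric(roi$F_background), length(roi$F))
  t <- roi$frame_times
  sel <- t >= nh4cl_window[1L] & t <= nh4cl_window[2L]
  if (!any(sel)) stop("no frames in NH4Cl window", call. = FALSE)
  Fmax <- mean(Fc[sel])
  F0 <- mean(Fc[t < t[1L] + baseline_window])
  if (Fmax <= F0)
    stop("Fmax <= F0: alkalinization failed", call. = FALSE)
  list(t = t, F_norm = Fc / Fmax, Fmax = Fmax)
}
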