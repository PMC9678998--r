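# Ratiometric Fura-2 calibration (Grynkiewicz) and SyGCaMP normalization.

#' Fura-2 calibration constants
#'
#' Bundles the constants of the ratiometric conversion: `Rmin`/`Rmax` are
#' the 340/380 ratios at 0 Ca2+ (5 mM EGTA) and at saturation (ionomycin),
#' `beta = F380max / F380min` is the ratio of 380-nm intensities at 0 Ca2+
#' versus saturation, and `Kd` is the indicator's dissociation constant.
#'
#' @param Kd Dissociation constant in nM (> 0); ~225 nM is typical for
#'   Fura-2 in vitro, but the pipeline expects a per-preparation value from
#'   [fit_fura_calibration()].
#' @param Rmin,Rmax Limiting ratios, `Rmax > Rmin > 0`.
#' @param beta `F380max / F380min` (> 0).
#' @param r2 Calibration-fit coefficient of determination (optional).
#' @param conc_grid Concentration grid used in the calibration, nM.
#' @return Object of class `"FuraCalibration"`.
#' @export
fura_calibration <- function(Kd, Rmin, Rmax, beta, r2 = NA_real_,
                             conc_grid = numeric(0)) {
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be > 0", call. = FALSE)
  if (!(Rmax > Rmin && Rmin > 0))
    stop("need Rmax > Rmin > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(Kd = Kd, Rmin = Rmin, Rmax = Rmax, beta = beta,
                 r2 = r2, conc_grid = as.numeric(conc_grid)),
            class = "FuraCalibration")
}

#' @export
print.FuraCalibration <- function(x, ...) {
  cat(sprintf("<FuraCalibration> Kd = %.4g nM, Rmin = %.4g, Rmax = %.4g, beta = %.4g, r2 = %.4g\n",
              x$Kd, x$Rmin, x$Rmax, x$beta, x$r2))
  invisible(x)
}

#' Convert a 340/380 ratio to calcium concentration
#'
#' Ratiometric conversion
#' `[Ca2+] = Kd * (R - Rmin) / (Rmax - R) * beta`, strictly increasing in R
#' on `(Rmin, Rmax)`. Ratios below `Rmin` are clamped to 0 nM with a
#' warning; ratios at or within `saturation_margin` of `Rmax` are flagged
#' invalid (`NA`) because the conversion diverges at saturation.
#'
#' @param R Numeric vector of measured 340/380 ratios.
#' @param calib A [fura_calibration()].
#' @param saturation_margin Fraction of the `Rmax - Rmin` span below `Rmax`
#'   treated as saturated (default 0.01).
#' @return Numeric vector of concentrations in nM (`NA` where saturated).
#' @examples
#' cal <- fura_calibration(Kd = 225, Rmin = 0.3, Rmax = 6, beta = 5)
#' grynkiewicz_concentration(cal$Rmin, cal)   # 0 nM
#' @export
grynkiewicz_concentration <- function(R, calib, saturation_margin = 0.01) {
  stopifnot(inherits(calib, "FuraCalibration"))
  R <- as.numeric(R)
  conc <- calib$Kd * (R - calib$Rmin) / (calib$Rmax - R) * calib$beta
  below <- R < calib$Rmin
  if (any(below, na.rm = TRUE)) {
    warning("ratio(s) below Rmin clamped to 0 nM", call. = FALSE)
    conc[below] <- 0
  }
  sat <- R >= calib$Rmax - saturation_margin * (calib$Rmax - calib$Rmin)
  conc[sat] <- NA_real_
  conc
}

#' Inverse conversion: ratio expected at a given calcium concentration
#'
#' Forward model used by the calibration fit and the simulator:
#' `R = (Rmin + Rmax * s) / (1 + s)` with `s = conc / (Kd * beta)`.
#'
#' @param conc Concentration(s) in nM (>= 0).
#' @param calib A [fura_calibration()].
#' @return Ratio(s) in `[Rmin, Rmax)`.
#' @export
grynkiewicz_ratio <- function(conc, calib) {
  stopifnot(inherits(calib, "FuraCalibration"))
  s <- as.numeric(conc) / (calib$Kd * calib$beta)
  (calib$Rmin + calib$Rmax * s) / (1 + s)
}

#' Fit the Fura-2 Kd from a calibration series
#'
#' Given known buffered Ca2+ concentrations and the measured ratios, plots
#' (internally) `log10[(R - Rmin)/(Rmax - R) * beta]` against `log10(conc)`
#' and reads the Kd at the x-intercept of the linear regression: there the
#' bracketed term equals 1, so `conc = Kd`. Points with R outside
#' `(Rmin, Rmax)` are excluded with a warning.
#'
#' @param known_conc Concentrations in nM (>= 3 usable points spanning the
#'   range of interest, e.g. 1 nM - 10 mM).
#' @param measured_R Ratios, same length.
#' @param Rmin,Rmax,beta Calibration constants (determined experimentally in
#'   0 Ca2+/EGTA and ionomycin/saturating Ca2+).
#' @return A [fura_calibration()] with fitted `Kd`, the regression `r2` and
#'   the concentration grid used.
#' @export
fit_fura_calibration <- function(known_conc, measured_R, Rmin, Rmax, beta) {
  known_conc <- as.numeric(known_conc)
  measured_R <- as.numeric(measured_R)
  stopifnot(length(known_conc) == length(measured_R))
  usable <- measured_R > Rmin & measured_R < Rmax & known_conc > 0
  if (any(!usable))
    warning(sprintf("%d calibration point(s) outside (Rmin, Rmax) excluded",
                    sum(!usable)), call. = FALSE)
  if (sum(usable) < 3L)
    stop("fewer than 3 usable calibration points", call. = FALSE)
  x <- log10(known_conc[usable])
  y <- log10((measured_R[usable] - Rmin) /
             (Rmax - measured_R[usable]) * beta)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (!is.finite(co[2L]) || co[2L] <= 0)
    stop("calibration regression has non-positive slope", call. = FALSE)
  log10_kd <- unname(-co[1L] / co[2L])  # x at y = 0
  fura_calibration(Kd = 10^log10_kd, Rmin = Rmin, Rmax = Rmax, beta = beta,
                   r2 = suppressWarnings(summary(fit)$r.squared),
                   conc_grid = known_conc[usable])
}

#' Basal SyGCaMP signal of a bouton
#'
#' Mean fluorescence over a non-stimulated baseline window normalized to the
#' mean local background signal (frames acquired at ~1 Hz; 15 s of baseline
#' in the standard protocol).
#'
#' @param roi An [roi_series()].
#' @param baseline_window Baseline span `c(t_start, t_end)` in s, or `NULL`
#'   to use all frames.
#' @return Unitless basal measure `mean(F) / mean(F_background)`.
#' @export
sygcamp_basal <- function(roi, baseline_window = NULL) {
  stopifnot(inherits(roi, "ROISeries"))
  sel <- if (is.null(baseline_window)) rep(TRUE, length(roi$F))
         else roi$frame_times >= baseline_window[1L] &
              roi$frame_times <= baseline_window[2L]
  if (!any(sel)) stop("no frames in baseline window", call. = FALSE)
  bg <- mean(rep_len(roi$F_background, length(roi$F))[sel])
  if (bg <= 0) stop("zero background: basal measure undefined", call. = FALSE)
  mean(roi$F[sel]) / bg
}

#' Evoked SyGCaMP response of a bouton
#'
#' Peak fluorescence in the stimulation window, basal-subtracted and
#' normalized to the baseline noise SD:
#' `(max F in stim_window - mean baseline F) / sd(baseline F)`.
#' The measure is invariant to camera gain. Reported per stimulation
#' frequency when boutons are probed with 2-s trains at 0.5-100 Hz.
#'
#' @param roi An [roi_series()].
#' @param stim_window `c(t_start, t_end)` of the stimulation/response window, s.
#' @param baseline_window `c(t_start, t_end)` of the pre-stimulus baseline;
#'   default all frames before `stim_window[1]`.
#' @return Unitless evoked response (peak over baseline in noise-SD units).
#' @export
sygcamp_evoked <- function(roi, stim_window, baseline_window = NULL) {
  stopifnot(inherits(roi, "ROISeries"))
  if (is.null(baseline_window))
    baseline_window <- c(roi$frame_times[1L], stim_window[1L])
  if (baseline_window[2L] > stim_window[1L])
    stop("baseline frames must precede stim_window", call. = FALSE)
  bsel <- roi$frame_times >= baseline_window[1L] &
          roi$frame_times < baseline_window[2L]
  ssel <- roi$frame_times >= stim_window[1L] &
          roi$frame_times <= stim_window[2L]
  if (!any(ssel)) stop("no frames in stim window", call. = FALSE)
  if (sum(bsel) < 2L) stop("need >= 2 baseline frames", call. = FALSE)
  basal <- mean(roi$F[bsel])
  s <- stats::sd(roi$F[bsel])
  if (s == 0) stop("zero baseline noise SD", call. = FALSE)
  (max(roi$F[ssel]) - basal) / s
}
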