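---
title: "Models and methods behind presynquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind presynquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynquant)
```

presynquant analyzes two kinds of raw data: voltage-clamp current sweeps
(pA, 10–20 kHz, inward currents negative at −70 mV) and fluorescence ROI
time series (Fura-2 340/380 pairs, SyGCaMP, synaptopHluorin). This vignette
explains each model the package fits, its assumptions, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the numerical choices a maintainer would want spelled out.
Throughout, "amplitude" means the positive magnitude |peak − baseline|.

## Miniature event detection

Spontaneous quantal events (mEPSCs/mIPSCs, recorded in TTX) are detected
with a threshold-amplitude-plus-threshold-area peak detector, the same
logic as the classical interactive detectors but with reproducible,
data-driven defaults:

* **Local baseline** — a trailing running median over `baseline_window`
  (default 50 ms). A median resists contamination by the events themselves
  as long as an event occupies less than half the window; with a ~5 ms
  decay this holds comfortably.
* **Amplitude threshold** — default 5× the robust noise SD, estimated as
  `mad(diff(x))/sqrt(2)`. Differencing first removes the slow baseline and
  the events, leaving (doubled) white noise; the MAD makes the estimate
  insensitive to the sparse large deflections.
* **Area threshold** — default amplitude threshold × 1 ms (pA·ms). Its job
  is to reject single-sample noise spikes that cross the amplitude
  threshold without carrying charge.
* **Event separation** — a new event is only opened once the signal has
  returned below 50% of the previous peak *and* the candidate lies outside
  the previous event's 10%-of-peak extent. Candidate maxima inside that
  extent are merged into the previous event (keeping the larger peak), so
  threshold-level jitter on a decay tail cannot fragment one event into
  several.

Onset is the last 10%-of-peak crossing before the peak; area integrates
the deviation over the 10%-extent. Kinetics are computed per event: the
10–90% rise time by linear interpolation of the level crossings, and the
decay time constant by a Levenberg–Marquardt fit of `A·exp(−t/τ)` to the
90→10% decay segment. An event whose decay is clipped by the end of the
sweep keeps its amplitude but is flagged `kinetics_ok = FALSE`.

Two accuracy notes. First, on a template whose decay is exactly
single-exponential the fitted τ is exact; on a bi-exponential PSC kernel
the residual fast (rise) component contaminates the early decay segment at
the 1–2% level, which is the accuracy floor of any single-exponential decay
fit started at 90% of peak. Second, with the 5σ default threshold, events
whose true amplitude sits *at* the threshold are detected with probability
near one half by construction; the ≥95% recall/precision operating point
quoted by the tests refers to events at or above 5σ in a population whose
mean amplitude is ~10σ, which is the regime the detector is meant for.

No filtering is applied before detection by default: the raw sweeps are
analyzed as recorded. A low-pass step can be added upstream by the caller
if a rig requires it.

## Evoked trains, RRP and release probability

`measure_evoked_amplitudes()` takes the mean of the 2 ms preceding each
stimulus as baseline and searches the peak from `artifact_blank` (default
2 ms, chosen to skip the brief somatic depolarization artifact) to the next
stimulus. For simulated traces, which have no artifact and whose PSC kernel
peaks ~1.3 ms after onset, the tests use a 0.5 ms blank.

The cumulative amplitude profile of a high-frequency train (40 Hz for
2–2.5 s) rises steeply while the readily releasable pool (RRP) empties,
then climbs linearly at the replenishment-limited rate. `estimate_rrp_pr()`
regresses the cumulative amplitude on stimulus time over the linear phase
— the half-open window [0.5, 1.0) s, i.e. stimuli 21–40 at 40 Hz — and
extrapolates back to t = 0 (the first stimulus). The intercept estimates
RRP_syn in pA and Pr = I₁/RRP_syn.

The estimator's bias is known in closed form under the generating model.
With `a₁ = N` sites, binomial release probability Pr, and a constant
refill of c sites per interval, the pool follows
`a_{k+1} = a_k(1 − Pr) + c`, so the cumulative profile approaches
`q·(N − c(1−Pr)/Pr) + q·c·f·t`. The intercept therefore *underestimates*
N·q by `c(1−Pr)/Pr` quanta — a margin that vanishes as Pr → 1, which is
precisely the method's stated assumption. The tests pin this closed form
(exact recovery at Pr = 1; bias −30/−13.3/−5 pA at Pr = 0.4/0.6/0.8 for
c = 2, q = 10 pA) and verify that the median estimate over 100 stochastic
cells at Pr = 0.8 stays within 10% of N·q.

A profile that never depresses (late amplitudes ≥ 90% of I₁) yields a
degenerate straight line through (0, I₁); since the fit window abscissa is
time with t = 0 at the first stimulus, the intercept then collapses to I₁
itself rather than 0. Such fits are flagged `valid = FALSE` — the method
requires a replenishment-limited steady state to exist.

Paired-pulse ratios are I₂/I₁ per two-stimulus sweep, aggregated per
inter-stimulus interval over the standard 20–1000 ms grid. In the
depletion model without replenishment, PPR = 1 − Pr exactly, which the
tests use as a closed-form oracle.

## Depression and recovery kinetics

Long trains (30 s at 10–20 Hz) are normalized to I₁ and fitted with
`SSC + A_f·e^(−t/τ_f) + A_s·e^(−t/τ_s)` (all parameters bounded below by
zero, τ_f < τ_s enforced by post-fit ordering); recovery at 0.1 Hz probing
is fitted with the mono-exponential rise `SSC − (SSC − y₀)·e^(−t/τ)`. The
steady-state current (SSC) is reported both as a fraction of I₁ and in pA,
since conventions differ between labs.

Fit initialization is deterministic: SSC seeds from the mean of the last
10% of points, time constants from log-linear pre-fits of the
SSC-subtracted residual. Because the bi-exponential surface has local
minima — and depression can be as fast as a single inter-stimulus interval
— the optimizer is started from a small fixed grid of time-constant pairs
(including one at the ISI scale) and the converged fit with the lowest
residual sum of squares is kept; mono- vs bi-exponential is then selected
by AIC, with the mono fit reported (slow component `NA`) when it wins or
when the bi-exponential fails. A perfectly flat train short-circuits to
SSC = mean(y) with zero exponential amplitude, since it carries no kinetic
information. On noiseless model data all generating parameters are
recovered to 1e-4 relative; with 5% multiplicative noise the median
recovery error over 100 seeds stays within 15% for every time constant.

## Fura-2 calibration and SyGCaMP normalization

The ratiometric conversion is
`[Ca²⁺] = K_d · (R − R_min)/(R_max − R) · β`, with β = F380_max/F380_min.
It is strictly increasing on (R_min, R_max) and diverges at saturation, so
ratios within 1% of R_max (configurable) are flagged invalid rather than
extrapolated, and ratios below R_min clamp to 0 nM with a warning.

`fit_fura_calibration()` implements the x-intercept procedure: regressing
`log10[(R − R_min)/(R_max − R)·β]` on `log10([Ca²⁺])` over a calibration
series (1 nM–10 mM), the K_d is the concentration at which the bracketed
term equals 1, i.e. the x value at y = 0. On noiseless forward data the
recovery is exact for any K_d between 10 nM and 10 µM; with 1% ratio noise
the median |Δlog₁₀K_d| stays below 0.05 over 100 seeds. R_min, R_max and β
are experimental inputs (0 Ca²⁺/EGTA and ionomycin/saturating Ca²⁺
conditions), not fitted.

SyGCaMP boutons are scored two ways, matching the two normalizations in
use: the **basal** measure is mean ROI fluorescence over a non-stimulated
window divided by the mean local background *signal*; the **evoked**
measure is the stimulation-window peak minus the basal mean, divided by
the baseline noise *SD*. Both are labelled explicitly rather than folded
into one number, and both are invariant to camera gain.

## synaptopHluorin

ΔF/F₀ uses F₀ = mean of the first 5 s before the stimulus after background
subtraction. The endocytosis constant τ_endo comes from a bounded
Levenberg–Marquardt fit of `plateau + A·e^(−t/τ)` starting at the
post-stimulus maximum (default decay window: to the end of the recording,
matching the ~90 s post-stimulus acquisition). Increasing segments, or
segments with no resolvable decay amplitude, are flagged invalid instead
of fitted. The train-recovery ratio is mean(post-conditioning probe peaks)
/ mean(pre-conditioning probe peaks) with all peaks normalized to the
first probe; the function accepts one or several post-conditioning probes,
covering both readings of the protocol. NH₄Cl normalization divides the
background-subtracted trace by the mean fluorescence over the perfusion
window and refuses to proceed when F_max ≤ F₀ (failed alkalinization). No
bleaching correction is applied by default, mirroring protocols that
insert rest periods instead of correcting.

## The synthetic generators

The generators exist to give every estimator a ground truth:

* **Minis** — homogeneous Poisson events at
  `mini_rate + slope·(resting_ca − 100 nM)`, bi-exponential kernels
  (rise 0.5 ms, decay 5 ms), lognormal quantal amplitudes (CV 0.3), white
  Gaussian noise. The linear Ca²⁺→rate coupling encodes the qualitative
  dependence of spontaneous release on resting Ca²⁺; no functional form is
  established in the literature, so the slope (default 0.005 Hz/nM) is a
  scenario knob, chosen so that the 110 → 265 nM resting-Ca²⁺ presets
  produce a ~2.5-fold frequency increase.
* **Trains** — the depletion + constant-replenishment recursion above, in
  expected (deterministic) or stochastic (binomial release, lognormal
  quantal sizes) mode. Replenishment is deterministic in both modes so the
  vesicle budget `Σ released ≤ N + c·T` holds exactly. The pool is capped
  at N.
* **Fura-2** — ratios from the exact forward Grynkiewicz relation;
  380-channel intensity interpolating between its 0-Ca²⁺ and saturated
  levels; multiplicative per-frame noise.
* **pHluorin** — instantaneous fluorescence steps of
  `exo_fraction·(F_max − F₀)` per burst, mono-exponential decay toward a
  residual plateau, optional NH₄Cl clamp to F_max.

Every simulator takes an explicit seed, never touches global RNG state
(the caller's `.Random.seed` is saved and restored), and is bit-reproducible.

What the generators do **not** emulate — and hence what passing tests do
not establish about real recordings: colored (1/f) recording noise and
line pickup, stimulus artifacts, series-resistance and space-clamp errors,
asynchronous release building up during trains, pool-size-dependent
replenishment, GCaMP nonlinearity and bleaching, and focus drift in
imaging. Parameter recovery here demonstrates correctness of the
estimators under their own model assumptions, not robustness to every
failure mode of an experiment.

## Problem sizes and defaults used in validation

The shipped tests and the acceptance script use: 40 Hz × 2 s trains
(80 stimuli) with N = 100, q = 10 pA and 2 sites replenished per interval;
100 simulated cells for the stochastic RRP check; 30 s @ 20 Hz grids
(600 points) for depression and 0.1 Hz probing over 120 s for recovery;
100 noise seeds for each fit-robustness check; and 50 recordings of 60 s
at 10 kHz (1 Hz event rate, 20 pA mean amplitude on 2 pA noise) for the
detector operating point. These sizes give sampling error comfortably
below the tolerances being asserted while keeping a full run in tens of
seconds.

## The orchestration layer

`run_pipeline()` executes configured stages over a manifest of cells
(files or simulation presets), derives one seed per cell from the run
seed, isolates failures per cell, and writes full-precision CSVs plus JSON
sidecars carrying a hash of the analysis configuration (the output
location is deliberately excluded from the hash so identical analyses are
byte-identical wherever they are written). Group summaries report n,
median, quartiles and mean ± SEM per genotype; pairwise comparisons use
Student's t only when every group passes a Shapiro–Wilk normality check
with n ≥ 8, and Mann–Whitney otherwise — statistical reporting is
delegated entirely to the standard routines, as it is convention, not a
contribution of this package.

The package's interface is its functions, this vignette, and
`scripts/acceptance.R`; analyses are driven from R or from YAML configs
via `run_pipeline()`, which covers the orchestration role a shell
interface would otherwise play.
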