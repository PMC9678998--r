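# Synthetic-data generators: every input the pipeline consumes, with ground
# truth, for parameter-recovery testing. All randomness flows through an
# explicit seed; the caller's RNG state is saved and restored.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed for per-cell streams (stays below 2^31)
.child_seed <- function(seed, k) (as.numeric(seed) * 48271 + k) %% 2147483647

#' Release-site model of a synapse
#'
#' Parameters of the depletion + constant-replenishment release model and of
#' the spontaneous (miniature) release process used by the simulators.
#' The evoked model: a pool of `N_sites` release sites, each releasing one
#' quantum of mean size `q_mean` with probability `Pr` per stimulus;
#' between stimuli the pool refills at `replenish_rate` sites/s, capped at
#' `N_sites`. Spontaneous release is a homogeneous Poisson process whose
#' rate increases linearly with resting Ca2+:
#' `rate = mini_rate + mini_rate_ca_slope * (resting_ca - 100)` (Hz, nM).
#'
#' @param N_sites Number of release sites (RRP size in quanta).
#' @param q_mean Mean quantal amplitude, pA.
#' @param q_cv Coefficient of variation of the lognormal quantal size.
#' @param Pr Release probability per site per stimulus, in (0, 1].
#' @param replenish_rate Constant pool refilling, sites/s.
#' @param mini_rate Spontaneous event rate at 100 nM resting Ca2+, Hz.
#' @param mini_rate_ca_slope Increase in spontaneous rate per nM resting
#'   Ca2+, Hz/nM.
#' @param resting_ca Resting terminal Ca2+ concentration, nM.
#' @param noise_sd Recording noise SD, pA.
#' @param psc_rise_tau,psc_decay_tau PSC kernel time constants, ms.
#' @param seed Default seed for simulations from this model.
#' @return Object of class `"SynapseModel"`.
#' @export
synapse_model <- function(N_sites = 100, q_mean = 10, q_cv = 0.3, Pr = 0.35,
                          replenish_rate = 80, mini_rate = 0.5,
                          mini_rate_ca_slope = 0.005, resting_ca = 110,
                          noise_sd = 2, psc_rise_tau = 0.5,
                          psc_decay_tau = 5, seed = 1L) {
  stopifnot(N_sites >= 1, q_mean > 0, q_cv >= 0, Pr > 0, Pr <= 1,
            replenish_rate >= 0, mini_rate >= 0, noise_sd >= 0,
            psc_rise_tau > 0, psc_decay_tau > psc_rise_tau)
  structure(as.list(environment()), class = "SynapseModel")
}

#' @export
print.SynapseModel <- function(x, ...) {
  cat(sprintf("<SynapseModel> N = %d sites, q = %.3g pA (CV %.2g), Pr = %.3g, replenish = %.3g sites/s\n",
              x$N_sites, x$q_mean, x$q_cv, x$Pr, x$replenish_rate))
  invisible(x)
}

#' Imaging forward model
#'
#' Constants of the fluorescence simulators: a Fura-2 calibration for the
#' ratiometric forward model, the SyGCaMP affinity, and the pHluorin
#' baseline/maximum and endocytosis time constant.
#'
#' @param calib A [fura_calibration()] (ground-truth constants).
#' @param gcamp_kd GCaMP6f dissociation constant, nM (375 nM).
#' @param f0 Baseline (surface + background-free) fluorescence, a.u.
#' @param fmax Total (alkalinized) fluorescence, a.u.; `fmax > f0 > 0`.
#' @param tau_endo Endocytosis/re-acidification time constant, s.
#' @param frame_rate Imaging frame rate, Hz.
#' @param noise_cv Multiplicative (shot/readout) noise CV per frame.
#' @param seed Default seed.
#' @return Object of class `"ImagingModel"`.
#' @export
imaging_model <- function(calib = fura_calibration(Kd = 225, Rmin = 0.3,
                                                   Rmax = 6, beta = 5),
                          gcamp_kd = 375, f0 = 100, fmax = 1000,
                          tau_endo = 12, frame_rate = 2, noise_cv = 0.02,
                          seed = 1L) {
  stopifnot(inherits(calib, "FuraCalibration"), frame_rate > 0,
            fmax > f0, f0 > 0, tau_endo > 0, noise_cv >= 0)
  structure(as.list(environment()), class = "ImagingModel")
}

# bi-exponential PSC kernel sampled at dt, normalized to unit peak
.psc_kernel <- function(rise_ms, decay_ms, dt, span_factor = 8) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  tk <- seq(0, span_factor * td, by = dt)
  k <- exp(-tk / td) - exp(-tk / tr)
  k / max(k)
}

.rlnorm_q <- function(n, q_mean, q_cv) {
  if (q_cv == 0) return(rep(q_mean, n))
  sdlog <- sqrt(log(1 + q_cv^2))
  stats::rlnorm(n, meanlog = log(q_mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a miniature-event recording
#'
#' Homogeneous Poisson events (rate set by the model's resting Ca2+, see
#' [synapse_model()]) drawn on `[0, duration)`, each an inward bi-exponential
#' PSC with lognormal amplitude, on white Gaussian noise. Deterministic
#' under a fixed seed.
#'
#' @param model A [synapse_model()].
#' @param duration Recording length, s.
#' @param dt Sampling interval, s (default 1e-4 = 10 kHz).
#' @param seed Integer seed (default `model$seed`).
#' @return List: `trace` (a [trace()], pA, inward events negative) and
#'   `events` (data frame of ground-truth `time` and `amplitude`).
#' @export
simulate_mini_trace <- function(model, duration, dt = 1e-4,
                                seed = model$seed) {
  stopifnot(inherits(model, "SynapseModel"), duration > 0, dt > 0)
  rate <- model$mini_rate +
    model$mini_rate_ca_slope * (model$resting_ca - 100)
  if (rate < 0) {
    warning("computed spontaneous rate < 0; clamped to 0", call. = FALSE)
    rate <- 0
  }
  .with_seed(seed, {
    n_ev <- stats::rpois(1L, rate * duration)
    times <- sort(stats::runif(n_ev, 0, duration))
    amps <- .rlnorm_q(n_ev, model$q_mean, model$q_cv)
    n <- round(duration / dt)
    x <- stats::rnorm(n, 0, model$noise_sd)
    if (n_ev > 0L) {
      kern <- .psc_kernel(model$psc_rise_tau, model$psc_decay_tau, dt)
      for (i in seq_len(n_ev)) {
        i0 <- floor(times[i] / dt) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        x[idx] <- x[idx] - amps[i] * kern[seq_along(idx)]
      }
    }
    list(trace = trace(x, dt = dt, label = "sim_minis", units = "pA"),
         events = data.frame(time = times, amplitude = amps))
  })
}

#' Simulate evoked amplitudes of a stimulation train
#'
#' Depletion + constant-replenishment model. With pool `a_1 = N_sites`:
#' released_k = `a_k * Pr` (expected mode) or `Binomial(floor(a_k), Pr)`
#' (stochastic); `amplitude_k = released_k * q`; between stimuli the pool
#' refills by `replenish_rate * ISI` sites, capped at `N_sites`, so the
#' cumulative number of released sites never exceeds
#' `N_sites + replenish_rate * train_duration`. In stochastic mode each
#' released quantum draws a lognormal size.
#'
#' @param model A [synapse_model()].
#' @param protocol A [stimulus_protocol()].
#' @param mode `"expected"` (deterministic) or `"stochastic"`.
#' @param seed Integer seed (stochastic mode).
#' @return Data frame: `index_in_train`, `stim_t`, `pool` (sites available
#'   before the stimulus), `released` (sites), `amplitude` (pA). The
#'   `stim_t`/`amplitude` columns feed [cumulative_profile()] directly.
#' @export
simulate_train <- function(model, protocol, mode = c("expected", "stochastic"),
                           seed = model$seed) {
  stopifnot(inherits(model, "SynapseModel"),
            inherits(protocol, "StimulusProtocol"))
  mode <- match.arg(mode)
  st <- protocol$stim_times
  nk <- length(st)
  run <- function() {
    pool <- numeric(nk); rel <- numeric(nk); amp <- numeric(nk)
    a <- model$N_sites
    for (k in seq_len(nk)) {
      pool[k] <- a
      r <- if (mode == "expected") a * model$Pr
           else stats::rbinom(1L, floor(a), model$Pr)
      rel[k] <- r
      amp[k] <- if (mode == "expected") r * model$q_mean
                else sum(.rlnorm_q(r, model$q_mean, model$q_cv))
      if (k < nk) {
        isi <- st[k + 1L] - st[k]
        a <- min(model$N_sites, a - r + model$replenish_rate * isi)
      }
    }
    data.frame(index_in_train = seq_len(nk), stim_t = st,
               pool = pool, released = rel, amplitude = amp)
  }
  if (mode == "expected") run() else .with_seed(seed, run())
}

#' Render simulated train amplitudes as a current trace
#'
#' Places an inward bi-exponential PSC of each simulated amplitude at its
#' stimulus time on white Gaussian noise, so the full amplitude-extraction
#' path ([measure_evoked_amplitudes()]) can be exercised against the
#' simulator's ground truth.
#'
#' @param model A [synapse_model()].
#' @param train Data frame from [simulate_train()].
#' @param dt Sampling interval, s.
#' @param pre,post Padding before the first / after the last stimulus, s.
#' @param noise_sd Noise SD, pA (default `model$noise_sd`).
#' @param seed Integer seed.
#' @return A [trace()] whose `t0` places the first stimulus at
#'   `train$stim_t[1]`.
#' @export
train_trace <- function(model, train, dt = 1e-4, pre = 0.05, post = 0.05,
                        noise_sd = model$noise_sd, seed = model$seed) {
  t0 <- train$stim_t[1L] - pre
  dur <- diff(range(train$stim_t)) + pre + post
  n <- round(dur / dt)
  x <- .with_seed(seed, stats::rnorm(n, 0, noise_sd))
  kern <- .psc_kernel(model$psc_rise_tau, model$psc_decay_tau, dt)
  for (k in seq_len(nrow(train))) {
    i0 <- round((train$stim_t[k] - t0) / dt) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] - train$amplitude[k] * kern[seq_along(idx)]
  }
  trace(x, dt = dt, t0 = t0, label = "sim_train", units = "pA")
}

#' Simulate a Fura-2 340/380 ROI pair at known concentrations
#'
#' Forward ratiometric model: for each true concentration the 340/380 ratio
#' solves the Grynkiewicz relation exactly ([grynkiewicz_ratio()]); the
#' 380-nm intensity interpolates between `F380max` (0 Ca2+) and
#' `F380min = F380max / beta` (saturation), and `F340 = R * F380`.
#' Per-frame multiplicative noise with CV `imaging$noise_cv`.
#'
#' @param true_conc Vector of true concentrations, nM (one ROI each).
#' @param imaging An [imaging_model()]; its `calib` provides the ground
#'   truth constants and `f0` sets `F380max`.
#' @param n_frames Frames per ROI.
#' @param seed Integer seed.
#' @return List with one element per concentration, each a list
#'   `(roi340, roi380, true_conc, true_R)` of [roi_series()] objects.
#' @export
simulate_fura <- function(true_conc, imaging, n_frames = 30,
                          seed = imaging$seed) {
  stopifnot(inherits(imaging, "ImagingModel"), all(true_conc >= 0))
  cal <- imaging$calib
  f380max <- imaging$f0
  f380min <- f380max / cal$beta
  ft <- (seq_len(n_frames) - 1L) / imaging$frame_rate
  .with_seed(seed, {
    lapply(seq_along(true_conc), function(i) {
      conc <- true_conc[i]
      R <- grynkiewicz_ratio(conc, cal)
      s <- conc / (cal$Kd * cal$beta)
      f380 <- (f380max + f380min * s) / (1 + s)
      f340 <- R * f380
      noise <- function(mu) mu * (1 + stats::rnorm(n_frames, 0, imaging$noise_cv))
      list(
        roi340 = roi_series(ft, noise(f340), roi_id = sprintf("roi%d_340", i),
                            channel = "340"),
        roi380 = roi_series(ft, noise(f380), roi_id = sprintf("roi%d_380", i),
                            channel = "380"),
        true_conc = conc, true_R = R)
    })
  })
}

#' Estimate the ratio of a simulated Fura ROI pair
#'
#' `R = mean(F340 - bg) / mean(F380 - bg)` over all frames.
#'
#' @param pair One element of [simulate_fura()]'s output (or any list with
#'   `roi340`, `roi380`).
#' @return The estimated 340/380 ratio.
#' @export
fura_ratio <- function(pair) {
  f340 <- pair$roi340$F - rep_len(pair$roi340$F_background,
                                  length(pair$roi340$F))
  f380 <- pair$roi380$F - rep_len(pair$roi380$F_background,
                                  length(pair$roi380$F))
  mean(f340) / mean(f380)
}

#' Simulate a synaptopHluorin ROI
#'
#' Each probe burst adds a fluorescence step
#' `dF = exo_fraction * (fmax - f0)` that decays mono-exponentially with
#' `tau_endo` toward a residual plateau (`plateau_frac` of the step). An
#' optional NH4Cl segment at the end clamps fluorescence to `fmax`.
#' Per-frame multiplicative noise with CV `imaging$noise_cv`.
#'
#' @param imaging An [imaging_model()].
#' @param protocol A [stimulus_protocol()] whose `stim_times` are the burst
#'   onsets; `labels` may mark entries `"probe"` (default) or `"train"`.
#' @param exo_fraction_per_probe Fraction of `(fmax - f0)` released per
#'   probe burst, in [0, 1].
#' @param exo_fraction_train Fraction released by a `"train"`-labelled burst.
#' @param plateau_frac Residual fraction of each step that does not decay.
#' @param duration Total recording length, s.
#' @param nh4cl_window Optional `c(t_start, t_end)` of NH4Cl perfusion, s.
#' @param seed Integer seed.
#' @return List: `roi` (an [roi_series()]) and `truth` (list of the
#'   generating parameters).
#' @export
simulate_phluorin <- function(imaging, protocol, exo_fraction_per_probe,
                              exo_fraction_train = NULL, plateau_frac = 0.1,
                              duration = NULL, nh4cl_window = NULL,
                              seed = imaging$seed) {
  stopifnot(inherits(imaging, "ImagingModel"),
            inherits(protocol, "StimulusProtocol"),
            exo_fraction_per_probe >= 0, exo_fraction_per_probe <= 1)
  if (is.null(exo_fraction_train)) exo_fraction_train <- exo_fraction_per_probe
  st <- protocol$stim_times
  lab <- protocol$labels %||% rep("probe", length(st))
  if (is.null(duration))
    duration <- max(st) + 6 * imaging$tau_endo
  if (!is.null(nh4cl_window)) duration <- max(duration, nh4cl_window[2L])
  ft <- seq(0, duration, by = 1 / imaging$frame_rate)
  dFmax <- imaging$fmax - imaging$f0
  F <- rep(imaging$f0, length(ft))
  for (j in seq_along(st)) {
    frac <- if (lab[j] == "train") exo_fraction_train else exo_fraction_per_probe
    dF <- frac * dFmax
    on <- ft >= st[j]
    td <- ft[on] - st[j]
    F[on] <- F[on] + dF * (plateau_frac +
                           (1 - plateau_frac) * exp(-td / imaging$tau_endo))
  }
  if (!is.null(nh4cl_window)) {
    inw <- ft >= nh4cl_window[1L] & ft <= nh4cl_window[2L]
    F[inw] <- imaging$fmax
  }
  Fn <- .with_seed(seed, F * (1 + stats::rnorm(length(F), 0, imaging$noise_cv)))
  list(
    roi = roi_series(ft, Fn, F_background = 0, roi_id = "sim_sypHy",
                     channel = "green"),
    truth = list(tau_endo = imaging$tau_endo, f0 = imaging$f0,
                 fmax = imaging$fmax, plateau_frac = plateau_frac,
                 step_dff = exo_fraction_per_probe * dFmax / imaging$f0,
                 stim_times = st)
  )
}

#' Simulate a SyGCaMP bouton ROI
#'
#' Bouton fluorescence proportional to the GCaMP saturation at the resting
#' Ca2+ concentration (`f0 * ca / (ca + gcamp_kd)`), with an optional
#' stimulus-evoked transient and multiplicative noise. The local background
#' is carried as a separate reference level in `F_background`, as measured
#' next to the bouton.
#'
#' @param imaging An [imaging_model()].
#' @param resting_ca Resting Ca2+ concentration, nM.
#' @param duration Recording length, s.
#' @param background Local background fluorescence, a.u.
#' @param stim_time Optional stimulus time, s.
#' @param transient_amp Evoked transient amplitude in baseline-noise-SD
#'   units' worth of fluorescence (a.u.) added at `stim_time`.
#' @param transient_tau Transient decay time constant, s.
#' @param seed Integer seed.
#' @return An [roi_series()] with `F_background` set.
#' @export
simulate_sygcamp <- function(imaging, resting_ca = 110, duration = 30,
                             background = 10, stim_time = NULL,
                             transient_amp = 0, transient_tau = 1,
                             seed = imaging$seed) {
  stopifnot(inherits(imaging, "ImagingModel"))
  ft <- seq(0, duration, by = 1 / imaging$frame_rate)
  sig <- imaging$f0 * resting_ca / (resting_ca + imaging$gcamp_kd)
  F <- rep(sig, length(ft))
  if (!is.null(stim_time)) {
    on <- ft >= stim_time
    F[on] <- F[on] + transient_amp * exp(-(ft[on] - stim_time) / transient_tau)
  }
  Fn <- .with_seed(seed, F * (1 + stats::rnorm(length(F), 0, imaging$noise_cv)))
  roi_series(ft, Fn, F_background = background, roi_id = "sim_sygcamp",
             channel = "green")
}

#' Named simulation presets
#'
#' Scenario presets bundling a [synapse_model()] with the matching
#' protocol: `"wt_rest"` / `"e373k_rest"` (resting terminals at 110 vs
#' 265 nM Ca2+, spontaneous release), `"depletion_40hz"` (40 Hz x 2 s
#' cumulative-analysis train) and `"recovery_20hz"` (30 s @ 20 Hz
#' depression followed by 0.1 Hz probing).
#'
#' @param name Preset name.
#' @param seed Seed stored in the model.
#' @return List with elements `model` (a `SynapseModel`) and, where
#'   applicable, `protocol` (a [stimulus_protocol()]).
#' @export
simulation_preset <- function(name = c("wt_rest", "e373k_rest",
                                       "depletion_40hz", "recovery_20hz"),
                              seed = 1L) {
  name <- match.arg(name)
  switch(name,
    wt_rest = list(model = synapse_model(resting_ca = 110, seed = seed)),
    e373k_rest = list(model = synapse_model(resting_ca = 265.4, seed = seed)),
    depletion_40hz = list(
      model = synapse_model(Pr = 0.8, replenish_rate = 80, seed = seed),
      protocol = train_protocol(40, 2)),
    recovery_20hz = list(
      model = synapse_model(Pr = 0.8, replenish_rate = 80, seed = seed),
      protocol = train_protocol(20, 30, probe_freq = 0.1,
                                probe_duration = 120))
  )
}
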