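test_that("pure noise below threshold yields no events", {
  set.seed(3)
  tr <- trace(rnorm(120000, sd = 1), dt = 1e-4)
  ev <- detect_minis(tr, amp_threshold = 8)
  expect_equal(nrow(ev), 0L)
})

test_that("injected events are recovered with onsets at the injection times", {
  times <- seq(0.5, 11.5, length.out = 10)
  tr <- make_mini_trace(times, rep(20, 10), duration = 12.5,
                        noise_sd = 2, seed = 5)
  ev <- detect_minis(tr)
  expect_equal(nrow(ev), 10L)
  expect_true(all(abs(ev$onset_t - times) < 1e-3))
  expect_true(all(ev$amplitude >= 5 * noise_sd(tr)))
})

test_that("detector errors on a trace shorter than the baseline window", {
  tr <- trace(rnorm(100), dt = 1e-4)
  expect_error(detect_minis(tr, baseline_window = 0.05), "shorter")
})

test_that("detector is baseline- and scale-equivariant", {
  times <- seq(0.4, 7.4, by = 1)
  tr <- make_mini_trace(times, rep(25, 8), duration = 8, noise_sd = 1.5,
                        seed = 9)
  ev <- detect_minis(tr, amp_threshold = 7.5, area_threshold = 7.5)
  # constant baseline offset leaves everything unchanged
  tr_off <- trace(tr$samples + 10, dt = tr$dt)
  ev_off <- detect_minis(tr_off, amp_threshold = 7.5, area_threshold = 7.5)
  expect_equal(ev_off$amplitude, ev$amplitude, tolerance = 1e-10)
  expect_equal(ev_off$onset_t, ev$onset_t)
  # doubling the signal doubles amplitudes and areas (thresholds doubled too)
  tr_x2 <- trace(tr$samples * 2, dt = tr$dt)
  ev_x2 <- detect_minis(tr_x2, amp_threshold = 15, area_threshold = 15)
  expect_equal(ev_x2$amplitude, 2 * ev$amplitude, tolerance = 1e-10)
  expect_equal(ev_x2$area, 2 * ev$area, tolerance = 1e-10)
  # time shift moves onsets rigidly
  tr_sh <- trace(tr$samples, dt = tr$dt, t0 = 3)
  ev_sh <- detect_minis(tr_sh, amp_threshold = 7.5, area_threshold = 7.5)
  expect_equal(ev_sh$onset_t, ev$onset_t + 3, tolerance = 1e-10)
})

test_that("kinetics recover the generating template exactly on noiseless data", {
  tr <- make_exact_event_trace(amp = 50, rise_ms = 0.5, decay_ms = 5)
  ev <- detect_minis(tr, amp_threshold = 8, kinetics = TRUE)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$kinetics_ok)
  expect_equal(ev$amplitude, 50, tolerance = 1e-12)
  expect_equal(ev$decay_tau, 5, tolerance = 1e-3)
  expect_equal(ev$rise_10_90, 0.4, tolerance = 1e-6)  # 80% of a linear rise
  # bi-exponential kernel: early decay carries the residual rise term, so
  # the fitted tau approaches the decay constant at percent-level accuracy
  tr_bi <- make_mini_trace(0.5, 50, duration = 2, noise_sd = 0)
  ev_bi <- detect_minis(tr_bi, amp_threshold = 8, kinetics = TRUE)
  expect_equal(ev_bi$decay_tau, 5, tolerance = 0.03)
})

test_that("events clipped by the trace end keep a missing-kinetics flag", {
  dt <- 1e-4
  tr <- make_exact_event_trace(amp = 40, t_on = 1.995, duration = 2, dt = dt)
  ev <- detect_minis(tr, amp_threshold = 8, kinetics = TRUE)
  expect_equal(nrow(ev), 1L)
  expect_false(ev$kinetics_ok)
  expect_true(is.na(ev$decay_tau))
})

test_that("amplitude is invariant under a baseline offset in event_kinetics", {
  tr <- make_exact_event_trace(amp = 30)
  ev <- detect_minis(tr, amp_threshold = 8)
  tr_off <- trace(tr$samples + 10, dt = tr$dt)
  k0 <- event_kinetics(tr, ev[1, ])
  k1 <- event_kinetics(tr_off, ev[1, ])
  expect_equal(k1$decay_tau, k0$decay_tau, tolerance = 1e-9)
})

test_that("mini_stats keeps frequency * duration = n exactly", {
  ev <- data.frame(onset_t = seq(1, 119, by = 5), peak_t = seq(1, 119, by = 5),
                   amplitude = 20, area = 50,
                   rise_10_90 = NA_real_, decay_tau = NA_real_,
                   kinetics_ok = NA)
  st <- mini_stats(ev, duration = 120)
  expect_identical(st$frequency * st$duration, as.numeric(st$n_events))
  expect_equal(st$frequency, 0.2)
  expect_error(mini_stats(ev, duration = 0), "duration")
})

test_that("mini_timecourse normalizes to the first window and flags empty baselines", {
  # stationary Poisson-like event stream: normalized frequencies near 1
  set.seed(21)
  ev_t <- sort(runif(400, 0, 1020))
  ev <- data.frame(onset_t = ev_t, peak_t = ev_t, amplitude = rlnorm(400, 3, 0.2),
                   area = 1, rise_10_90 = NA_real_, decay_tau = NA_real_,
                   kinetics_ok = NA)
  win <- rbind(c(0, 120), c(120, 420), c(420, 720), c(720, 1020))
  tc <- mini_timecourse(ev, win)
  expect_equal(tc$norm_frequency[1L], 1)
  expect_true(all(abs(tc$norm_frequency - 1) < 0.35))

  # halving the rate after t = 120 halves the normalized frequency
  set.seed(22)
  ev2_t <- sort(c(runif(240, 0, 120), runif(240 / 2 * (900 / 120), 120, 1020)))
  ev2 <- ev; ev2 <- ev2[0, ]
  ev2 <- data.frame(onset_t = ev2_t, peak_t = ev2_t, amplitude = 20, area = 1,
                    rise_10_90 = NA_real_, decay_tau = NA_real_, kinetics_ok = NA)
  tc2 <- mini_timecourse(ev2, win)
  expect_true(all(abs(tc2$norm_frequency[-1L] - 0.5) < 0.1))

  # empty first window: normalization flagged undefined
  ev3 <- ev[ev$peak_t > 120, , drop = FALSE]
  expect_warning(tc3 <- mini_timecourse(ev3, win), "normalization")
  expect_true(all(is.na(tc3$norm_frequency)))
  # malformed windows rejected
  expect_error(mini_timecourse(ev, rbind(c(0, 120), c(100, 200))), "disjoint")
})
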