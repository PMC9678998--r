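test_that("simulators are bit-reproducible under a fixed seed", {
  m <- synapse_model()
  a <- simulate_mini_trace(m, duration = 5, seed = 42)
  b <- simulate_mini_trace(m, duration = 5, seed = 42)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$events, b$events)
  c <- simulate_mini_trace(m, duration = 5, seed = 43)
  expect_false(identical(a$trace$samples, c$trace$samples))

  p <- train_protocol(40, 2)
  s1 <- simulate_train(m, p, mode = "stochastic", seed = 7)
  s2 <- simulate_train(m, p, mode = "stochastic", seed = 7)
  expect_identical(s1, s2)

  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_mini_trace(m, duration = 1, seed = 5))
  expect_identical(runif(1), before)
})

test_that("zero-rate model produces a pure-noise trace with no events", {
  m <- synapse_model(mini_rate = 0, mini_rate_ca_slope = 0, noise_sd = 2)
  sim <- simulate_mini_trace(m, duration = 10, seed = 1)
  expect_equal(nrow(sim$events), 0L)
  expect_lt(abs(mean(sim$trace$samples)), 0.2)
  expect_equal(sd(sim$trace$samples), 2, tolerance = 0.05)
  # negative computed rate clamps to zero with a warning
  m2 <- synapse_model(mini_rate = 0.1, mini_rate_ca_slope = 0.005,
                      resting_ca = 10)
  expect_warning(sim2 <- simulate_mini_trace(m2, duration = 5, seed = 1),
                 "clamped")
  expect_equal(nrow(sim2$events), 0L)
})

test_that("event counts follow the Poisson law at the configured rate", {
  m <- synapse_model(mini_rate = 0.5, mini_rate_ca_slope = 0, q_cv = 0,
                     noise_sd = 0)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_mini_trace(m, duration = 600, dt = 0.01, seed = s)$events)
  }, numeric(1))
  expect_equal(mean(counts), 300, tolerance = 0.03)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("raising resting calcium raises the spontaneous rate by slope x delta", {
  m_wt <- synapse_model(mini_rate = 0.5, mini_rate_ca_slope = 0.005,
                        resting_ca = 110, noise_sd = 0)
  m_mut <- synapse_model(mini_rate = 0.5, mini_rate_ca_slope = 0.005,
                         resting_ca = 265, noise_sd = 0)
  n_wt <- mean(vapply(1:60, function(s)
    nrow(simulate_mini_trace(m_wt, 200, dt = 0.01, seed = s)$events),
    numeric(1)))
  n_mut <- mean(vapply(1:60, function(s)
    nrow(simulate_mini_trace(m_mut, 200, dt = 0.01, seed = 500 + s)$events),
    numeric(1)))
  # expected rates: 0.55 vs 1.325 Hz
  expect_equal((n_mut - n_wt) / 200, 0.005 * 155, tolerance = 0.12)
})

test_that("train simulator reproduces its closed forms", {
  # Pr = 1 with 2 sites replenished per ISI
  m <- synapse_model(N_sites = 100, q_mean = 10, q_cv = 0, Pr = 1,
                     replenish_rate = 80)
  trn <- simulate_train(m, train_protocol(40, 2), mode = "expected")
  expect_equal(trn$amplitude, c(1000, rep(20, 79)))
  # Pr = 0.5 without replenishment: geometric decay of the pool
  m2 <- synapse_model(N_sites = 64, q_mean = 5, q_cv = 0, Pr = 0.5,
                      replenish_rate = 0)
  trn2 <- simulate_train(m2, train_protocol(40, 0.25), mode = "expected")
  expect_equal(trn2$amplitude, 64 * 5 * 0.5 * 0.5^(0:9), tolerance = 1e-12)
  # pool conservation: total release never exceeds N + replenished sites
  expect_lt(sum(trn2$released), 64 + 1e-9)
})

test_that("stochastic trains conserve the vesicle budget across seeds", {
  m <- synapse_model(N_sites = 100, q_mean = 10, Pr = 0.8, replenish_rate = 80)
  p <- train_protocol(40, 2)
  total_time <- max(p$stim_times) - min(p$stim_times)
  for (s in 1:20) {
    trn <- simulate_train(m, p, mode = "stochastic", seed = s)
    expect_lte(sum(trn$released), 100 + 80 * total_time + 1)
    expect_true(all(trn$pool <= 100 + 1e-9))
  }
})

test_that("Fura forward simulation inverts through the calibration module", {
  im <- imaging_model(noise_cv = 0)
  expect_equal(fura_ratio(simulate_fura(0, im)[[1]]), im$calib$Rmin,
               tolerance = 1e-12)
  grid <- 10^seq(0, 7, length.out = 12)
  sims <- simulate_fura(grid, im)
  est <- vapply(sims, function(p)
    grynkiewicz_concentration(fura_ratio(p), im$calib,
                              saturation_margin = 0), numeric(1))
  expect_true(all(abs(est - grid) / grid < 1e-9))
  # with 2% frame noise the recovered concentrations track the truth
  im2 <- imaging_model(noise_cv = 0.02)
  grid2 <- 10^seq(1, 4, length.out = 6)  # away from the saturated ends
  sims2 <- simulate_fura(grid2, im2, n_frames = 50, seed = 77)
  est2 <- vapply(sims2, function(p)
    grynkiewicz_concentration(fura_ratio(p), im2$calib), numeric(1))
  expect_true(all(abs(est2 - grid2) / grid2 < 0.15))
})

test_that("pHluorin simulator honors its null and round-trip cases", {
  im <- imaging_model(noise_cv = 0)
  p <- stimulus_protocol(10, train_freq = 100)
  flat <- simulate_phluorin(im, p, exo_fraction_per_probe = 0,
                            duration = 60)
  expect_true(all(abs(flat$roi$F - im$f0) < 1e-9))
  sim <- simulate_phluorin(im, p, exo_fraction_per_probe = 0.25,
                           plateau_frac = 0, duration = 90)
  fe <- fit_endocytosis(dff(sim$roi, baseline_window = 5))
  expect_equal(fe$tau_endo, im$tau_endo, tolerance = 1e-6)
})

test_that("presets encode the study scenarios", {
  wt <- simulation_preset("wt_rest")
  mut <- simulation_preset("e373k_rest")
  expect_equal(wt$model$resting_ca, 110)
  expect_equal(mut$model$resting_ca, 265.4)
  dep <- simulation_preset("depletion_40hz")
  expect_equal(length(dep$protocol$stim_times), 80L)
  rec <- simulation_preset("recovery_20hz")
  expect_equal(rec$protocol$probe_freq, 0.1)
  expect_equal(length(rec$protocol$stim_times), 612L)
})
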