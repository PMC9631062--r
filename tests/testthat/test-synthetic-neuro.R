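# Ground-truth membrane-potential simulators.

test_that("current steps obey Ohm's law and exponential relaxation", {
  cell <- cell_model(resistance_MOhm = 100, tau_membrane_ms = 10)
  prot <- step_protocol(100, baseline_s = 0.1, step_duration_s = 0.1,
                        mode = "current", inter_step_s = 0)
  v <- simulate_step_response(prot, cell, sample_rate = 20000, tail_s = 0)
  # steady state of a long step: 100 pA * 100 MOhm = +10 mV; at 10 tau the
  # asymptote is reached far below the 1e-9 mV bookkeeping tolerance for
  # the segment-target arithmetic
  cell_fast <- cell_model(resistance_MOhm = 100, tau_membrane_ms = 2)
  v2 <- simulate_step_response(prot, cell_fast, 20000, tail_s = 0)
  expect_equal(v2$values[length(v2$values)], -70 + 10, tolerance = 1e-9)
  # 63.2% of the steady-state deflection one time constant after onset
  k_on <- round(0.1 * 20000)                # onset sample (0-based)
  k_tau <- round(0.11 * 20000)
  frac <- (v$values[k_tau + 1] - v$values[k_on + 1]) / 10
  expect_equal(frac, 1 - exp(-1), tolerance = 0.01)
})

test_that("the default protocol durations follow the stated arithmetic", {
  cell <- cell_model()
  v0 <- simulate_step_response(default_current_steps(inter_step_s = 0),
                               cell, 20000, tail_s = 0)
  expect_equal(length(v0$values) / 20000, 0.1 + 5 * 0.1)   # contiguous
  v1 <- simulate_step_response(default_current_steps(), cell, 20000,
                               tail_s = 0)
  expect_equal(length(v1$values) / 20000, 0.1 + 5 * 0.1 + 4 * 0.07)
  expect_equal(attr(v1, "step_onsets_s"), c(0.1, 0.27, 0.44, 0.61, 0.78))
  expect_equal(attr(v1, "steady_dV_mV"), c(-20, -10, 0, 10, 20))
  # every default measurement window sits inside its step
  win <- default_step_windows("current")
  expect_silent(measure_dv(v1, win))
  expect_error(simulate_step_response(default_current_steps(), cell, 500),
               ">= 1 kHz")
})

test_that("voltage-clamp steps follow the command from holding", {
  v <- simulate_step_response(default_voltage_steps(), cell_model(), 20000)
  expect_equal(attr(v, "steady_dV_mV"), c(-50, -30, -10, 10, 30) - (-70))
  expect_equal(v$values[1], -70)
  dv <- measure_dv(v, default_step_windows("voltage"))
  expect_equal(dv, attr(v, "steady_dV_mV"), tolerance = 0.05)
})

test_that("pulse trains place one spike per pulse at the right times", {
  cell <- cell_model()
  s25 <- simulate_spike_train(pulse_train_protocol(frequency_Hz = 25,
                                                   onset_s = 0),
                              cell, 20000)
  expect_equal(s25$spikes$n, 10)
  # pulse onsets 0, 40, ..., 360 ms; peaks one rise time later
  expect_equal(s25$spikes$times - cell$spike_rise_ms / 1000 + 1 / 20000,
               seq(0, 0.36, by = 0.04), tolerance = 1e-6)
  s100 <- simulate_spike_train(pulse_train_protocol(frequency_Hz = 100),
                               cell, 20000)
  expect_equal(unique(round(diff(s100$spikes$times), 6)), 0.01)
  s1 <- simulate_spike_train(pulse_train_protocol(n_pulses = 1), cell, 20000)
  expect_equal(s1$spikes$n, 1)
  expect_error(simulate_spike_train(pulse_train_protocol(frequency_Hz = 240,
                                                         pulse_width_ms = 2),
                                    cell, 20000),
               "overlap")
})

test_that("ensemble simulation is reproducible and respects its parameters", {
  m <- ensemble_model(n_cells = 2, duration_s = 5, burst_rate_Hz = 1,
                      sync_jitter_ms = 0, independent_rate_Hz = 0, seed = 4)
  a <- simulate_ensemble(m, sample_rate = 2000)
  b <- simulate_ensemble(m, sample_rate = 2000)
  expect_identical(a[[1]]$trace$values, b[[1]]$trace$values)  # replay
  expect_identical(a[[2]]$spikes$times, b[[2]]$spikes$times)
  # zero jitter, no background: burst spike sets identical across cells
  expect_equal(a[[1]]$spikes$times, a[[2]]$spikes$times, tolerance = 1e-9)
})

test_that("background firing matches the Poisson count oracle", {
  # burst_rate 0, 5 Hz background, 10 s: expected 50 spikes per cell,
  # observed within 3*sqrt(50) across seeds
  for (seed in 1:5) {
    m <- ensemble_model(n_cells = 2, duration_s = 10, burst_rate_Hz = 0,
                        independent_rate_Hz = 5, seed = seed,
                        subthreshold_common_amp_mV = 0)
    sim <- simulate_ensemble(m, sample_rate = 1000)
    for (cl in sim)
      expect_lt(abs(cl$spikes$n - 50), 3 * sqrt(50))
  }
  expect_warning(
    simulate_ensemble(ensemble_model(duration_s = 0.5, burst_rate_Hz = 0.4,
                                     seed = 1), 1000),
    "shorter than one expected burst")
})

test_that("pairwise synchrony decreases with jitter", {
  sync_frac <- function(jitter) {
    frac <- numeric(3)
    for (s in 1:3) {
      m <- ensemble_model(n_cells = 2, duration_s = 20, burst_rate_Hz = 1,
                          sync_jitter_ms = jitter, independent_rate_Hz = 0,
                          seed = 100 + s)
      sim <- simulate_ensemble(m, sample_rate = 2000)
      t1 <- sim[[1]]$spikes$times; t2 <- sim[[2]]$spikes$times
      if (!length(t2)) { frac[s] <- 0; next }
      frac[s] <- mean(vapply(t2, function(x) min(abs(x - t1)) <= 0.002, TRUE))
    }
    mean(frac)
  }
  f <- vapply(c(0, 1, 5, 20), sync_frac, 0)
  expect_true(all(diff(f) <= 1e-9))
  expect_gt(f[1], 0.99)
  expect_lt(f[4], 0.5)
})

test_that("voltage traces round-trip through CSV export", {
  v <- voltage_trace(c(-70, -69.5, -70.2, -70), 1000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltage_csv(v, path)
  v2 <- read_voltage_csv(path)
  expect_equal(v2$values, v$values)
  expect_equal(v2$sample_rate, 1000)
})
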