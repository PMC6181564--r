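test_that("with no stimulus drive the model is a homogeneous Poisson process", {
  stim <- quick_stimulus(duration = 100, kind = "constant", seed = 1)
  n <- neuron_spec(baseline_rate = 30, gain_coefficient = 0,
                   gain_exponent = 0, am_sensitivity = 0, seed = 2)
  spikes <- simulate_neuron(stim, n)
  expect_equal(length(spikes$times), 3000, tolerance = 3 * sqrt(3000) / 3000)

  # spike-count mean and variance over 1 s windows agree (Fano ~ 1)
  counts <- tabulate(floor(spikes$times) + 1L, nbins = 100)
  fano <- stats::var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / 99))
})

test_that("programmed envelope modulation is recovered from the cycle histogram", {
  # G0 * f^beta * depth = 10 * 1^0.4 * 0.2 = 2 Hz at a 1 Hz envelope
  stim <- quick_stimulus(duration = 400, envelope_frequency = 1, seed = 3)
  n <- neuron_spec(baseline_rate = 30, gain_coefficient = 10,
                   gain_exponent = 0.4, am_sensitivity = 0, seed = 4)
  spikes <- simulate_neuron(stim, n)
  res <- analyze_unit(spikes, 1, 0.2)
  se <- sqrt(2 * 30 / 400)  # shot-noise standard error of the amplitude
  expect_lt(abs(res$fit$amplitude - 2), 3 * se)
})

test_that("simulation is reproducible by seed and stochastic across seeds", {
  stim <- quick_stimulus(duration = 50, seed = 5)
  n1 <- neuron_spec(30, 50, 0.4, seed = 6)
  expect_identical(simulate_neuron(stim, n1)$times,
                   simulate_neuron(stim, n1)$times)
  n2 <- neuron_spec(30, 50, 0.4, seed = 7)
  t1 <- simulate_neuron(stim, n1)$times
  t2 <- simulate_neuron(stim, n2)$times
  expect_false(identical(t1, t2))
  # same programmed gain within a generous confidence band
  g1 <- analyze_unit(spike_train(t1, 50), 0.5, 0.2)$gain
  g2 <- analyze_unit(spike_train(t2, 50), 0.5, 0.2)$gain
  prog <- 50 * 0.5^0.4
  expect_lt(abs(g1 - prog) / prog, 0.3)
  expect_lt(abs(g2 - prog) / prog, 0.3)
})

test_that("full pipeline recovers programmed gain within 10% across (G0, beta)", {
  cases <- list(c(g0 = 100, beta = 0), c(g0 = 150, beta = 0.4),
                c(g0 = 80, beta = -0.3))
  for (k in seq_along(cases)) {
    g0 <- cases[[k]]["g0"]; beta <- cases[[k]]["beta"]
    f <- 0.5
    stim <- quick_stimulus(duration = 200, envelope_frequency = f,
                           seed = 20 + k)
    n <- neuron_spec(baseline_rate = 80, gain_coefficient = g0,
                     gain_exponent = beta, am_sensitivity = 0,
                     seed = 30 + k)
    gain <- analyze_unit(simulate_neuron(stim, n), f, 0.2)$gain
    expect_lt(abs(gain - g0 * f^beta) / (g0 * f^beta), 0.1)
  }
})

test_that("refractory period is enforced and invalid rates rejected", {
  stim <- quick_stimulus(duration = 30, kind = "constant", seed = 8)
  n <- neuron_spec(200, 0, 0, refractory = 0.004, seed = 9)
  spikes <- simulate_neuron(stim, n)
  expect_true(all(diff(spikes$times) >= 0.004))
  n_bad <- neuron_spec(3000, 0, 0, seed = 10)
  expect_error(simulate_neuron(stim, n_bad), "invalid")
})

test_that("condition presets encode the published tuning structure", {
  expect_equal(condition_preset("control_ell")$gain_exponent, 0.4)
  expect_equal(condition_preset("multipolar")$gain_exponent, 0.4)
  expect_equal(condition_preset("np_inactivated")$gain_exponent, 0)
  expect_equal(condition_preset("pet_inactivated")$gain_exponent, 0)
  expect_equal(condition_preset("stellate")$gain_exponent, 0)
  ctrl <- condition_preset("control_ell")
  expect_lt(condition_preset("np_inactivated")$gain_coefficient,
            ctrl$gain_coefficient)
  expect_gt(condition_preset("pet_inactivated")$gain_coefficient,
            ctrl$gain_coefficient)
  # custom passthrough
  cu <- condition_preset("custom", baseline_rate = 12, gain_coefficient = 7,
                         gain_exponent = 0.1)
  expect_equal(cu$baseline_rate, 12)
  expect_equal(cu$gain_coefficient, 7)
  expect_equal(cu$gain_exponent, 0.1)
  expect_error(condition_preset("no_such_condition"), "unknown")
})
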