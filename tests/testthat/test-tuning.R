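test_that("gain is modulation amplitude over envelope amplitude", {
  fit <- structure(list(amplitude = 2), class = "sinewave_fit")
  expect_equal(compute_gain(fit, 0.2), 10)
  fit0 <- structure(list(amplitude = 0), class = "sinewave_fit")
  expect_equal(compute_gain(fit0, 0.2), 0)
  expect_error(compute_gain(fit, 0), "positive")
})

test_that("gain is independent of modulation depth for a linear neuron", {
  gains <- vapply(c(0.1, 0.2), function(depth) {
    stim <- quick_stimulus(duration = 200, envelope_frequency = 0.5,
                           depth = depth, seed = 11)
    n <- neuron_spec(80, 100, 0.4, am_sensitivity = 0, seed = 12)
    analyze_unit(simulate_neuron(stim, n), 0.5, depth)$gain
  }, numeric(1))
  expect_lt(abs(gains[1] - gains[2]) / gains[2], 0.15)
})

test_that("power-law fit recovers exact and noisy exponents", {
  f <- six_freqs
  exact <- fit_power_law(tuning_curve(f, 2 * f^0.4))
  expect_equal(exact$exponent, 0.4, tolerance = 1e-10)
  expect_equal(exact$log10_coefficient, log10(2), tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  flat <- fit_power_law(tuning_curve(f, rep(5, 6)))
  expect_equal(flat$exponent, 0, tolerance = 1e-10)
  expect_equal(flat$r_squared, 1)  # zero residual, zero variance

  set.seed(99)
  exps <- replicate(100, {
    g <- 2 * f^0.4 * exp(rnorm(6, 0, 0.05))
    fit_power_law(tuning_curve(f, g))$exponent
  })
  expect_equal(mean(exps), 0.4, tolerance = 0.05)

  expect_warning(fit_power_law(tuning_curve(f, c(0, 0, 0, 1, 2, 3))),
                 "zero gain")
  expect_error(suppressWarnings(
    fit_power_law(tuning_curve(f, c(0, 0, 0, 0, 2, 3)))), "at least 3")
})

test_that("response power is gain squared times the natural spectrum", {
  f <- six_freqs
  # gain f^0.4 against alpha = -0.8 whitens exactly
  wr <- predict_response_power(tuning_curve(f, f^0.4))
  expect_equal(wr$response_power, rep(1, 6), tolerance = 1e-12)
  expect_equal(wr$white_index, 1, tolerance = 1e-12)

  # flat gain passes the stimulus spectrum through
  wr2 <- predict_response_power(tuning_curve(f, rep(1, 6)))
  expect_equal(wr2$response_power, f^-0.8, tolerance = 1e-12)

  # log-log slope identity: 2*beta + alpha, for several beta and alpha
  for (beta in c(0, 0.25, 0.4)) {
    for (alpha in c(-0.8, -0.5)) {
      wr3 <- predict_response_power(tuning_curve(f, 3 * f^beta), alpha)
      slope <- stats::coef(stats::lm(log10(wr3$response_power) ~
                                       log10(f)))[2]
      expect_equal(unname(slope), 2 * beta + alpha, tolerance = 1e-9)
    }
  }
})

test_that("whitening index: flat spectra score 1, decaying spectra less", {
  f <- six_freqs
  expect_identical(white_index(f, rep(7, 6)), 1)
  expect_identical(white_index(f, rep(0.001, 6)), 1)

  # frozen hand-trapezoid oracle for f^-0.8 on the six frequencies:
  # areas 0.43239 + 0.49668 + 0.80475 + 0.37499 + 0.28235 over
  # 0.95 * max(10.9856) = 0.229117
  expect_equal(white_index(f, f^-0.8), 0.229117, tolerance = 1e-4)

  # scale invariance
  p <- f^-1.3
  expect_equal(white_index(f, p), white_index(f, 1e6 * p))
  expect_equal(white_index(f, p), white_index(f, 1e-6 * p))

  # monotone in the spectral exponent for decaying spectra
  wis <- vapply(c(-2, -1.5, -1, -0.5, 0),
                function(g) white_index(f, f^g), numeric(1))
  expect_true(all(diff(wis) > 0))
  expect_equal(wis[5], 1)

  # single non-zero endpoint: closed-form half-bin over full range
  p_end <- c(0, 0, 0, 0, 0, 1)
  expect_equal(white_index(f, p_end),
               (0.25 * (0 + 1) / 2) / (1 * (1 - 0.05)))

  expect_error(white_index(f, rep(0, 6)), "all zero")
  expect_error(white_index(f, c(-1, 1, 1, 1, 1, 1)), ">= 0")
  expect_error(white_index(1, 1), "at least 2")
})

test_that("sensitivity change is the percent gain change", {
  expect_equal(sensitivity_change(1.5, 1), 50)
  expect_equal(sensitivity_change(1, 1), 0)
  expect_equal(sensitivity_change(0.5, 1), -50)
  expect_equal(sensitivity_change(c(2, 1), c(1, 2)), c(100, -50))
  expect_error(sensitivity_change(1, 0), "positive")
})
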