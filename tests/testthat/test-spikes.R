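test_that("threshold crossing detects constructed pulses exactly", {
  fs <- 10000
  v <- numeric(fs * 2)
  centers <- round(seq(0.1, 1.9, length.out = 10) * fs)
  for (c0 in centers) v[c0:(c0 + 9)] <- 1  # 1 ms pulses
  st <- detect_spikes(v, fs, 0.5)
  expect_equal(length(st$times), 10)
  expect_equal(st$times, (centers - 1) / fs, tolerance = 2e-3)

  expect_equal(length(detect_spikes(numeric(fs), fs, 0.5)$times), 0)
  expect_error(detect_spikes(numeric(fs), fs, -1), "always above threshold")
  expect_error(detect_spikes(c(0, NA, 1), fs, 0.5), "non-finite")
})

test_that("cycle histogram conserves spikes and folds phase correctly", {
  # spikes only in phase [0, 0.5): second half exactly zero
  f <- 0.5
  times <- sort(unlist(lapply(0:19, function(k) k / f + c(0.1, 0.4, 0.8))))
  st <- spike_train(times, 40)
  h <- cycle_histogram(st, f, n_bins = 16)
  expect_equal(sum(h$rate / (h$n_bins * f) * h$n_cycles), h$n_spikes)
  expect_true(all(h$rate[h$bin_centers >= 0.5] == 0))
  expect_true(any(h$rate[h$bin_centers < 0.5] > 0))

  # homogeneous train: flat histogram, near-zero fitted amplitude
  stim <- quick_stimulus(duration = 200, kind = "constant", seed = 1)
  n <- neuron_spec(30, 0, 0, seed = 2)
  h2 <- cycle_histogram(simulate_neuron(stim, n), 0.5, 32)
  expect_equal(mean(h2$rate), 30, tolerance = 0.05)
  fit <- fit_sinewave(h2)
  expect_lt(fit$amplitude, 3 * sqrt(2 * 30 / 200))

  expect_error(cycle_histogram(st, 0.03), "2 complete")
})

test_that("sinewave fit equals the fundamental Fourier component", {
  phi <- (1:32 - 0.5) / 32
  h <- list(rate = 40 + 6 * sin(2 * pi * phi), bin_centers = phi)
  fit <- fit_sinewave(h)
  expect_equal(fit$amplitude, 6, tolerance = 1e-12)
  expect_equal(fit$offset, 40, tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-10)

  flat <- fit_sinewave(list(rate = rep(25, 32), bin_centers = phi))
  expect_equal(flat$amplitude, 0, tolerance = 1e-12)
  expect_equal(flat$offset, 25)

  # a second harmonic is orthogonal to the fundamental fit
  h2 <- list(rate = 40 + 6 * sin(2 * pi * phi + 0.7) +
               3 * sin(4 * pi * phi), bin_centers = phi)
  fit2 <- fit_sinewave(h2)
  expect_equal(fit2$amplitude, 6, tolerance = 1e-9)
  expect_equal(fit2$phase, 0.7, tolerance = 1e-9)

  # equals the complex Fourier coefficient of a random histogram
  set.seed(42)
  r <- rexp(32, 1 / 20)
  c1 <- 2 * mean(r * exp(-2i * pi * phi))
  fitr <- fit_sinewave(list(rate = r, bin_centers = phi))
  expect_equal(fitr$amplitude, Mod(c1), tolerance = 1e-9)
})

test_that("rate filter cutoffs follow the tabulated mapping", {
  expect_equal(rate_filter_cutoff(0.05), 0.2)
  expect_equal(rate_filter_cutoff(0.1), 0.35)
  expect_equal(rate_filter_cutoff(0.2), 0.75)
  expect_equal(rate_filter_cutoff(0.5), 1.5)
  expect_equal(rate_filter_cutoff(0.75), 2.5)
  expect_equal(rate_filter_cutoff(1), 3.5)
  expect_warning(co <- rate_filter_cutoff(0.3), "not in the tabulated set")
  expect_equal(co, 0.75)
  expect_error(rate_filter_cutoff(0.3, strict = TRUE), "no tabulated")
})

test_that("filtered rate preserves the mean rate of a homogeneous train", {
  stim <- quick_stimulus(duration = 120, kind = "constant", seed = 3)
  n <- neuron_spec(30, 0, 0, seed = 4)
  spikes <- simulate_neuron(stim, n)
  tr <- filtered_rate(spikes, 500, 0.5)
  mid <- tr$time > 5 & tr$time < 115
  expect_equal(mean(tr$rate[mid]), 30, tolerance = 1 / 30)
  expect_equal(mean(tr$rate[mid]),
               length(spikes$times) / spikes$duration, tolerance = 0.02)
})

test_that("cycle-histogram and filtered-rate gain estimates agree within 10%", {
  for (f in six_freqs) {
    dur <- max(100, 20 / f)
    stim <- quick_stimulus(duration = dur, envelope_frequency = f,
                           seed = round(1000 * f))
    n <- condition_preset("control_ell", seed = round(2000 * f))
    spikes <- simulate_neuron(stim, n)
    g_hist <- analyze_unit(spikes, f, 0.2)$gain
    tr <- filtered_rate(spikes, 500, f)
    trim <- 3 / tr$cutoff
    keep <- tr$time > trim & tr$time < dur - trim
    X <- cbind(1, sin(2 * pi * f * tr$time[keep]),
               cos(2 * pi * f * tr$time[keep]))
    co <- stats::lm.fit(X, tr$rate[keep])$coefficients
    g_filt <- sqrt(sum(co[2:3]^2)) / 0.2
    expect_lt(abs(g_filt - g_hist) / g_hist, 0.1)
  }
})

test_that("STA recovers constructed spike-stimulus alignment", {
  fs <- 1000  # peaks of a 10 Hz sine land exactly on this grid
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  am <- sin(2 * pi * 10 * t)
  peaks <- seq(0.025, 59, by = 0.1)  # every positive peak
  sta <- compute_sta(am, fs, spike_train(peaks, 60), window = 2)
  expect_equal(sta$mean_stimulus[sta$lags == 0], 1, tolerance = 1e-6)
  expect_equal(sta$peak_to_peak, 2, tolerance = 1e-6)
  # the STA is itself a 10 Hz sinusoid
  expect_equal(sta$mean_stimulus, cos(2 * pi * 10 * sta$lags),
               tolerance = 1e-6)
})

test_that("STA magnitude reflects AM sensitivity and vanishes under independence", {
  stim <- quick_stimulus(duration = 100, kind = "constant", seed = 5)
  n_am <- neuron_spec(60, 0, 0, am_sensitivity = 30, seed = 6)
  n_0 <- neuron_spec(60, 0, 0, am_sensitivity = 0, seed = 6)
  sta_am <- compute_sta(stim$am, 500, simulate_neuron(stim, n_am))
  sta_0 <- compute_sta(stim$am, 500, simulate_neuron(stim, n_0))
  expect_gt(sta_am$peak_to_peak, sta_0$peak_to_peak)

  # unmodulated neuron's STA is consistent with a spike-shuffle null
  spikes <- simulate_neuron(stim, n_0)
  ptp_null <- vapply(1:200, function(i) {
    set.seed(i)
    sh <- sort(runif(length(spikes$times), 0, 100))
    compute_sta(stim$am, 500, spike_train(unique(sh), 100))$peak_to_peak
  }, numeric(1))
  expect_lt(sta_0$peak_to_peak, stats::quantile(ptp_null, 0.95) * 1.05)
})

test_that("STA percent-of-control is a plain ratio with guarded input", {
  mk <- function(ptp) structure(list(peak_to_peak = ptp),
                                class = "sta_result")
  expect_equal(sta_percent_of_control(mk(2), mk(2)), 100)
  expect_equal(sta_percent_of_control(mk(1), mk(2)), 50)
  expect_error(sta_percent_of_control(mk(1), mk(0)), "positive")
})
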