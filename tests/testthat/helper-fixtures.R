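# Shared fixture builders for the test suite.  Everything is generated in
# code; no stored data.

six_freqs <- envelope_frequency_set()

quick_stimulus <- function(duration = 60, sample_rate = 500,
                           envelope_frequency = 0.5, depth = 0.2,
                           kind = "sinusoidal", seed = 1) {
  make_stimulus(stimulus_spec(
    duration = duration, sample_rate = sample_rate, envelope_kind = kind,
    envelope_frequency = envelope_frequency, modulation_depth = depth,
    seed = seed))
}

# Smoothed periodogram power near a target frequency (Hz)
power_near <- function(x, fs, f0, halfwidth = 0.5) {
  p <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                         detrend = FALSE, plot = FALSE)
  mean(p$spec[abs(p$freq - f0) <= halfwidth])
}

# Brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments (independent oracle for wilcoxon_signed_rank)
wilcoxon_p_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  mu <- sum(r) / 2
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
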