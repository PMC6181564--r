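# Synthetic stimulus generation: band-limited amplitude-modulated (AM) noise
# carriers whose amplitude is further modulated by a slow envelope.
# Amplitudes are in dimensionless contrast units with baseline 1, so neural
# gain downstream has units Hz per unit contrast.

#' Supported sinusoidal envelope frequencies (Hz)
#'
#' The canonical six-frequency set used throughout: 0.05, 0.1, 0.2, 0.5,
#' 0.75 and 1 Hz, the behaviorally relevant range of movement envelopes.
#' @export
envelope_frequency_set <- function() c(0.05, 0.1, 0.2, 0.5, 0.75, 1)

#' Stimulus specification
#'
#' Describes one synthetic stimulus: a 5--15 Hz Gaussian-noise AM carrier
#' (4th-order Butterworth band-pass, zero-phase) modulated by either a
#' sinusoidal envelope, a naturalistic power-law envelope, or no envelope.
#'
#' @param duration recording length in seconds.
#' @param sample_rate sampling rate in Hz; must exceed twice the upper AM
#'   band edge.
#' @param am_band numeric length-2, AM carrier band in Hz (default 5--15).
#' @param am_filter_order Butterworth prototype order for the carrier
#'   band-pass (default 4).
#' @param envelope_kind `"sinusoidal"`, `"natural"`, or `"constant"`.
#' @param envelope_frequency envelope frequency in Hz for the sinusoidal
#'   kind; conventionally one of [envelope_frequency_set()].
#' @param modulation_depth envelope modulation depth as a fraction of the
#'   baseline amplitude (default 0.20); for the natural kind this is the RMS
#'   contrast.  Must lie in `[0, 1)`.
#' @param natural_exponent spectral slope of the natural envelope power
#'   spectrum (default -0.8).
#' @param seed integer RNG seed or `NULL`.
#' @return an object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(duration = 60, envelope_frequency = 0.1, seed = 1)
#' stim <- make_stimulus(spec)
#' @export
stimulus_spec <- function(duration,
                          sample_rate = 2000,
                          am_band = c(5, 15),
                          am_filter_order = 4,
                          envelope_kind = c("sinusoidal", "natural", "constant"),
                          envelope_frequency = 0.1,
                          modulation_depth = 0.2,
                          natural_exponent = -0.8,
                          seed = NULL) {
  envelope_kind <- match.arg(envelope_kind)
  stop_if_not_scalar(duration, "duration")
  stop_if_not_scalar(sample_rate, "sample_rate")
  stop_if_not_scalar(modulation_depth, "modulation_depth")
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (length(am_band) != 2L || am_band[1] <= 0 || am_band[2] <= am_band[1]) {
    stop("`am_band` must be increasing positive band edges", call. = FALSE)
  }
  if (sample_rate <= 2 * am_band[2]) {
    stop("`sample_rate` too low: must exceed twice the upper AM band edge",
         call. = FALSE)
  }
  if (modulation_depth < 0 || modulation_depth >= 1) {
    stop("`modulation_depth` must lie in [0, 1): a depth >= 1 would drive ",
         "the envelope negative", call. = FALSE)
  }
  if (envelope_kind == "sinusoidal") {
    stop_if_not_scalar(envelope_frequency, "envelope_frequency")
    if (envelope_frequency <= 0) {
      stop("`envelope_frequency` must be positive", call. = FALSE)
    }
    if (duration < 2 / envelope_frequency) {
      stop("`duration` must cover at least 2 full envelope cycles",
           call. = FALSE)
    }
  }
  structure(
    list(duration = duration, sample_rate = sample_rate, am_band = am_band,
         am_filter_order = am_filter_order, envelope_kind = envelope_kind,
         envelope_frequency = envelope_frequency,
         modulation_depth = modulation_depth,
         natural_exponent = natural_exponent, seed = seed),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %gs @ %g Hz | AM %g-%g Hz | %s envelope", x$duration,
    x$sample_rate, x$am_band[1], x$am_band[2], x$envelope_kind))
  if (x$envelope_kind == "sinusoidal") {
    cat(sprintf(" %g Hz, depth %g", x$envelope_frequency, x$modulation_depth))
  } else if (x$envelope_kind == "natural") {
    cat(sprintf(" slope %g, contrast %g", x$natural_exponent,
                x$modulation_depth))
  }
  cat("\n")
  invisible(x)
}

#' Generate a band-limited noise AM carrier
#'
#' Zero-mean Gaussian noise band-pass filtered to the AM band (5--15 Hz by
#' default) with a zero-phase Butterworth response, normalized to unit RMS.
#'
#' @param spec a [stimulus_spec()].
#' @return numeric waveform of length `duration * sample_rate`.
#' @export
generate_am_noise <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration * spec$sample_rate)
  filt <- butter_bandpass(spec$sample_rate, spec$am_band[1], spec$am_band[2],
                          spec$am_filter_order)
  x <- with_local_seed(spec$seed, stats::rnorm(n))
  x <- signal::filtfilt(filt, x)
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Generate a naturalistic power-law envelope
#'
#' A positive envelope whose one-sided power spectrum over 0.05--1 Hz decays
#' as `f^alpha` with `alpha = spec$natural_exponent`, built by shaping white
#' Gaussian noise in the frequency domain (shaping band 0.02--2 Hz, zero
#' outside), then scaled to RMS contrast `modulation_depth` and offset to
#' mean 1.  Realizations that would go non-positive are rejected rather than
#' clipped, because clipping distorts the spectrum.
#'
#' @param spec a [stimulus_spec()] with `envelope_kind = "natural"`.
#' @param shape_band band (Hz) over which the spectrum is shaped.
#' @return numeric envelope vector (mean 1, strictly positive).
#' @export
generate_natural_envelope <- function(spec, shape_band = c(0.02, 2)) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$envelope_kind != "natural") {
    stop("`spec$envelope_kind` must be \"natural\"", call. = FALSE)
  }
  n <- round(spec$duration * spec$sample_rate)
  freq <- seq(0, n - 1) / n * spec$sample_rate
  freq[freq > spec$sample_rate / 2] <-
    freq[freq > spec$sample_rate / 2] - spec$sample_rate
  w <- with_local_seed(spec$seed, stats::rnorm(n))
  amp <- ifelse(abs(freq) >= shape_band[1] & abs(freq) <= shape_band[2],
                abs(freq)^(spec$natural_exponent / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  if (stats::sd(x) == 0) stop("degenerate shaping band", call. = FALSE)
  x <- x / stats::sd(x) * spec$modulation_depth
  env <- 1 + x
  if (any(env <= 0)) {
    stop("requested modulation depth drives the natural envelope ",
         "non-positive; lower `modulation_depth`", call. = FALSE)
  }
  env
}

#' Apply an envelope to an AM carrier
#'
#' For the sinusoidal kind the envelope is `1 + depth * sin(2 pi f t)`; the
#' stimulus is the carrier multiplied by the envelope.  The returned
#' [stimulus set][make_stimulus] stores both.
#'
#' @param am carrier waveform from [generate_am_noise()] at
#'   `spec$sample_rate`.
#' @param spec a [stimulus_spec()].
#' @return an object of class `stimulus_set` with fields `time`, `am`
#'   (modulated waveform), `envelope`, and `spec`.
#' @export
apply_envelope <- function(am, spec) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(am))
  n <- round(spec$duration * spec$sample_rate)
  if (length(am) != n) {
    stop("`am` was not generated at `spec` length/sample rate", call. = FALSE)
  }
  t <- seq(0, n - 1) / spec$sample_rate
  env <- switch(spec$envelope_kind,
    sinusoidal = 1 + spec$modulation_depth *
      sin(2 * pi * spec$envelope_frequency * t),
    natural = generate_natural_envelope(spec),
    constant = rep(1, n))
  structure(list(time = t, am = am * env, envelope = env, spec = spec),
            class = "stimulus_set")
}

#' Build a complete stimulus from a specification
#'
#' Convenience wrapper: [generate_am_noise()] then [apply_envelope()].
#'
#' @param spec a [stimulus_spec()].
#' @return a `stimulus_set`.
#' @export
make_stimulus <- function(spec) apply_envelope(generate_am_noise(spec), spec)

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d samples (%.1f s @ %g Hz), %s envelope\n",
              length(x$am), x$spec$duration, x$spec$sample_rate,
              x$spec$envelope_kind))
  invisible(x)
}

#' Measure the envelope modulation depth of a stimulus
#'
#' Reads the slow envelope out of a modulated noise waveform as the
#' magnitude of the analytic signal, low-pass smoothed (zero-phase), then
#' fits a sinusoid at the envelope frequency; the measured depth is the
#' fitted amplitude divided by the mean of the smoothed envelope.  Edges are
#' trimmed to avoid filter transients.
#'
#' @param stim a `stimulus_set` with a sinusoidal envelope.
#' @param smooth_cutoff low-pass smoothing cutoff in Hz (default 2; above
#'   the highest envelope frequency, below the AM band).
#' @param edge_trim seconds trimmed at each end (default 2).
#' @return measured modulation depth as a fraction of baseline.
#' @export
measure_modulation_depth <- function(stim, smooth_cutoff = 2, edge_trim = 2) {
  stopifnot(inherits(stim, "stimulus_set"))
  spec <- stim$spec
  if (spec$envelope_kind != "sinusoidal") {
    stop("modulation-depth readout assumes a sinusoidal envelope",
         call. = FALSE)
  }
  fs <- spec$sample_rate
  env_raw <- Mod(analytic_signal(stim$am))
  filt <- butter_lowpass(fs, smooth_cutoff, order = 2)
  env_smooth <- filtfilt_keep_dc(filt, env_raw)
  keep <- stim$time >= edge_trim & stim$time <= (spec$duration - edge_trim)
  t <- stim$time[keep]
  y <- env_smooth[keep]
  s <- sin(2 * pi * spec$envelope_frequency * t)
  c_ <- cos(2 * pi * spec$envelope_frequency * t)
  fit <- stats::lm.fit(cbind(1, s, c_), y)
  amp <- sqrt(sum(fit$coefficients[2:3]^2))
  amp / mean(y)
}
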