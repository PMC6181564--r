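# Spike-train processing: threshold detection on voltage traces, cycle
# histograms folded at the envelope frequency, sinewave (fundamental
# Fourier) fits, low-pass filtered firing-rate traces, and spike-triggered
# averages.

#' Spike train container
#'
#' @param times spike times in seconds, strictly ascending, within
#'   `[0, duration)`.
#' @param duration recording duration in seconds.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  stop_if_not_scalar(duration, "duration")
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times))) stop("non-finite spike times", call. = FALSE)
    if (any(diff(times) <= 0)) {
      stop("spike times must be strictly ascending", call. = FALSE)
    }
    if (times[1] < 0 || times[length(times)] >= duration) {
      stop("spike times must lie in [0, duration)", call. = FALSE)
    }
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.2f Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Detect spikes in an extracellular voltage trace
#'
#' High-pass filters the trace (100 Hz, 8th-order Butterworth, zero-phase)
#' and returns the times at which the filtered signal crosses `threshold`
#' from below, refined by linear interpolation between samples.
#'
#' @param voltage numeric voltage trace (finite values).
#' @param sample_rate sampling rate in Hz (>= 5 kHz recommended).
#' @param threshold detection threshold, same units as `voltage`.
#' @param highpass_cutoff high-pass cutoff in Hz (default 100).
#' @param filter_order Butterworth order (default 8).
#' @return a [spike_train()].
#' @export
detect_spikes <- function(voltage, sample_rate, threshold,
                          highpass_cutoff = 100, filter_order = 8) {
  stopifnot(is.numeric(voltage), length(voltage) > 1)
  if (any(!is.finite(voltage))) {
    stop("voltage trace contains non-finite samples", call. = FALSE)
  }
  stop_if_not_scalar(sample_rate, "sample_rate")
  stop_if_not_scalar(threshold, "threshold")
  filt <- butter_highpass(sample_rate, highpass_cutoff, filter_order)
  v <- signal::filtfilt(filt, voltage)
  if (all(v > threshold)) {
    stop("signal is always above threshold: no upward crossings can exist",
         call. = FALSE)
  }
  n <- length(v)
  below <- v[-n] < threshold & v[-1] >= threshold
  idx <- which(below)
  times <- (idx - 1 + (threshold - v[idx]) / (v[idx + 1] - v[idx])) /
    sample_rate
  spike_train(times, n / sample_rate)
}

#' Cycle histogram of a spike train at the envelope frequency
#'
#' Folds spikes after `t_start` by envelope phase, keeping only complete
#' cycles, and converts bin counts to rates in Hz.
#'
#' @param spikes a [spike_train()].
#' @param envelope_frequency folding frequency in Hz.
#' @param n_bins number of phase bins (default 32; >= 8).
#' @param t_start analysis start time in seconds (default 0).  Passing one
#'   envelope period discards the onset transient.
#' @return an object of class `cycle_histogram` with `bin_centers` (phase in
#'   cycles), `rate` (Hz), `n_bins`, `n_cycles`, `envelope_frequency`.
#' @export
cycle_histogram <- function(spikes, envelope_frequency, n_bins = 32,
                            t_start = 0) {
  stopifnot(inherits(spikes, "spike_train"))
  stop_if_not_scalar(envelope_frequency, "envelope_frequency")
  if (n_bins < 8) stop("`n_bins` must be >= 8", call. = FALSE)
  n_cycles <- floor((spikes$duration - t_start) * envelope_frequency)
  if (n_cycles < 2) {
    stop("fewer than 2 complete envelope cycles after `t_start`",
         call. = FALSE)
  }
  t_end <- t_start + n_cycles / envelope_frequency
  st <- spikes$times[spikes$times >= t_start & spikes$times < t_end]
  phase <- ((st - t_start) * envelope_frequency) %% 1
  bin <- pmin(floor(phase * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  bin_seconds <- 1 / (n_bins * envelope_frequency)
  structure(
    list(n_bins = n_bins, bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
         rate = counts / (n_cycles * bin_seconds), n_cycles = n_cycles,
         envelope_frequency = envelope_frequency, n_spikes = length(st)),
    class = "cycle_histogram")
}

#' Fit a sinewave to a cycle histogram
#'
#' Closed-form fundamental Fourier projection: `rate(phi) ~ offset + A *
#' sin(2 pi phi + theta)` with `A >= 0`.  For uniform bins this equals the
#' least-squares sinewave fit, and `A` is the firing-rate modulation
#' amplitude.
#'
#' @param hist a [cycle_histogram()], or any list with fields `rate` and
#'   `bin_centers` (phase in cycles) -- continuous traces folded into bins
#'   work the same way.
#' @return an object of class `sinewave_fit` with `amplitude`, `phase`,
#'   `offset`, `residual_rms` (all in Hz except `phase`, radians).
#' @export
fit_sinewave <- function(hist) {
  r <- hist$rate
  phi <- hist$bin_centers
  stopifnot(is.numeric(r), length(r) == length(phi), all(is.finite(r)))
  offset <- mean(r)
  a <- 2 * mean(r * cos(2 * pi * phi))
  b <- 2 * mean(r * sin(2 * pi * phi))
  amplitude <- sqrt(a^2 + b^2)
  phase <- atan2(a, b)
  fitted <- offset + amplitude * sin(2 * pi * phi + phase)
  structure(
    list(amplitude = amplitude, phase = phase, offset = offset,
         residual_rms = sqrt(mean((r - fitted)^2))),
    class = "sinewave_fit")
}

#' @export
print.sinewave_fit <- function(x, ...) {
  cat(sprintf(
    "<sinewave_fit> offset %.2f Hz, amplitude %.3f Hz, phase %.2f rad\n",
    x$offset, x$amplitude, x$phase))
  invisible(x)
}

#' Low-pass cutoff paired with each envelope frequency
#'
#' The firing-rate low-pass cutoffs used for the six envelope frequencies:
#' 0.2, 0.35, 0.75, 1.5, 2.5 and 3.5 Hz for envelope frequencies 0.05, 0.1,
#' 0.2, 0.5, 0.75 and 1 Hz.
#'
#' @param envelope_frequency envelope frequency in Hz.
#' @param strict if `TRUE`, frequencies outside the six-frequency set are an
#'   error; otherwise the nearest mapping is used with a warning.
#' @return cutoff frequency in Hz.
#' @export
rate_filter_cutoff <- function(envelope_frequency, strict = FALSE) {
  freqs <- envelope_frequency_set()
  cutoffs <- c(0.2, 0.35, 0.75, 1.5, 2.5, 3.5)
  i <- match(envelope_frequency, freqs)
  if (is.na(i)) {
    if (strict) {
      stop(sprintf("envelope frequency %g Hz has no tabulated cutoff",
                   envelope_frequency), call. = FALSE)
    }
    i <- which.min(abs(freqs - envelope_frequency))
    warning(sprintf(
      "envelope frequency %g Hz not in the tabulated set; using the cutoff for %g Hz",
      envelope_frequency, freqs[i]), call. = FALSE)
  }
  cutoffs[i]
}

#' Low-pass filtered firing-rate trace
#'
#' Builds a delta train (each spike contributes unit area, 1/dt at its
#' nearest sample) and low-pass filters it with a zero-phase 2nd-order
#' Butterworth at the cutoff tabulated for the envelope frequency, giving a
#' time-resolved firing rate in Hz.
#'
#' @param spikes a [spike_train()].
#' @param sample_rate output sampling rate in Hz.
#' @param envelope_frequency envelope frequency (selects the cutoff).
#' @param strict passed to [rate_filter_cutoff()].
#' @return an object of class `rate_trace` with `time`, `rate` (Hz),
#'   `sample_rate`, `cutoff`.
#' @export
filtered_rate <- function(spikes, sample_rate, envelope_frequency,
                          strict = FALSE) {
  stopifnot(inherits(spikes, "spike_train"))
  cutoff <- rate_filter_cutoff(envelope_frequency, strict = strict)
  n <- round(spikes$duration * sample_rate)
  idx <- pmin(pmax(round(spikes$times * sample_rate) + 1L, 1L), n)
  delta <- tabulate(idx, nbins = n) * sample_rate
  filt <- butter_lowpass(sample_rate, cutoff, order = 2)
  structure(
    list(time = (seq_len(n) - 1) / sample_rate,
         rate = filtfilt_keep_dc(filt, delta), sample_rate = sample_rate,
         cutoff = cutoff),
    class = "rate_trace")
}

#' Spike-triggered average of the stimulus
#'
#' Mean stimulus waveform in a window centered on each spike (default 2 s,
#' lags -1..+1 s).  Spikes whose window falls outside the trace are skipped
#' rather than zero-padded.
#'
#' @param am stimulus waveform (contrast units).
#' @param sample_rate sampling rate of `am` in Hz.
#' @param spikes a [spike_train()].
#' @param window total window length in seconds (default 2).
#' @return an object of class `sta_result` with `lags` (s), `mean_stimulus`,
#'   `peak_to_peak`, `n_spikes`.
#' @export
compute_sta <- function(am, sample_rate, spikes, window = 2) {
  stopifnot(is.numeric(am), inherits(spikes, "spike_train"))
  half <- round(window / 2 * sample_rate)
  idx <- round(spikes$times * sample_rate) + 1L
  idx <- idx[idx - half >= 1L & idx + half <= length(am)]
  if (length(idx) == 0L) {
    stop("no spikes with a complete STA window", call. = FALSE)
  }
  lag_idx <- seq(-half, half)
  sta <- vapply(lag_idx, function(l) mean(am[idx + l]), numeric(1))
  structure(
    list(lags = lag_idx / sample_rate, mean_stimulus = sta,
         peak_to_peak = max(sta) - min(sta), n_spikes = length(idx)),
    class = "sta_result")
}

#' STA peak-to-peak as a percentage of control
#'
#' The control STA is normalized to 100%; the manipulated STA is reported
#' relative to it.
#'
#' @param sta_drug,sta_control [compute_sta()] results.
#' @return percentage (100 = unchanged).
#' @export
sta_percent_of_control <- function(sta_drug, sta_control) {
  stopifnot(inherits(sta_drug, "sta_result"),
            inherits(sta_control, "sta_result"))
  if (sta_control$peak_to_peak <= 0) {
    stop("control STA peak-to-peak must be positive", call. = FALSE)
  }
  100 * sta_drug$peak_to_peak / sta_control$peak_to_peak
}
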