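# Behavioral analysis: extract the time-varying EOD frequency from an EOD
# signal via zero crossings, and compute behavioral gain per envelope
# frequency with the same cycle-average/sinewave-fit machinery used for
# spikes.

#' Behavior trace container
#'
#' @param time time vector in seconds.
#' @param eod_frequency EOD frequency in Hz, same length.
#' @param sample_rate sampling rate of the trace in Hz.
#' @param lowpass_cutoff cutoff (Hz) of the low-pass used to extract the
#'   trace (stored for filter-gain correction).
#' @return an object of class `behavior_trace`.
#' @export
behavior_trace <- function(time, eod_frequency, sample_rate,
                           lowpass_cutoff = NA_real_) {
  stopifnot(is.numeric(time), is.numeric(eod_frequency),
            length(time) == length(eod_frequency))
  structure(
    list(time = time, eod_frequency = eod_frequency,
         sample_rate = sample_rate, lowpass_cutoff = lowpass_cutoff),
    class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %d samples @ %g Hz, mean EOD %.1f Hz\n",
              length(x$time), x$sample_rate, mean(x$eod_frequency)))
  invisible(x)
}

#' Time-varying EOD frequency from an EOD signal
#'
#' Finds upward zero crossings by linear interpolation, builds a delta
#' sequence (each crossing contributes unit area, so the low-pass output of
#' an f0 crossing train equals f0), and low-pass filters it with a
#' zero-phase 2nd-order Butterworth at `lowpass_cutoff` (0.05 Hz by
#' default).  For numerical conditioning the delta sequence is first
#' anti-alias filtered and decimated to `intermediate_rate` before the very
#' low final cutoff is applied; the extracted trace is returned at the
#' intermediate rate.
#'
#' @param eod_signal an `eod_signal` object from [simulate_behavior()], or a
#'   numeric sampled trace (then `sample_rate` is required).
#' @param sample_rate sampling rate in Hz (ignored for `eod_signal`
#'   objects).
#' @param lowpass_cutoff final low-pass cutoff in Hz (default 0.05).
#' @param intermediate_rate decimated rate in Hz; the default (`NULL`)
#'   chooses `min(200, crossing rate / 8)` so that the carrier line and its
#'   modulation sidebands are fully removed by the anti-alias stage instead
#'   of folding into the envelope band.
#' @return a [behavior_trace()].
#' @export
eod_frequency <- function(eod_signal, sample_rate = NULL,
                          lowpass_cutoff = 0.05, intermediate_rate = NULL) {
  if (inherits(eod_signal, "eod_signal")) {
    x <- eod_signal$signal
    fs <- eod_signal$sample_rate
  } else {
    stopifnot(is.numeric(eod_signal))
    if (is.null(sample_rate)) {
      stop("`sample_rate` is required for a raw numeric trace",
           call. = FALSE)
    }
    x <- eod_signal
    fs <- sample_rate
  }
  if (any(!is.finite(x))) stop("non-finite samples", call. = FALSE)
  n <- length(x)
  up <- which(x[-n] < 0 & x[-1] >= 0)
  if (length(up) < 100) {
    stop("fewer than 100 upward zero crossings: not an oscillatory EOD ",
         "signal", call. = FALSE)
  }
  crossings <- (up - 1 + (0 - x[up]) / (x[up + 1] - x[up])) / fs
  if (is.null(intermediate_rate)) {
    crossing_rate <- length(crossings) / (n / fs)
    intermediate_rate <- min(200, crossing_rate / 8)
  }
  # unit-area delta sequence at the full rate
  idx <- pmin(pmax(round(crossings * fs) + 1L, 1L), n)
  delta <- tabulate(idx, nbins = n) * fs
  # stage 1: anti-alias and decimate to the intermediate rate
  k <- max(1L, round(fs / intermediate_rate))
  fs_i <- fs / k
  if (k > 1L) {
    aa <- butter_lowpass(fs, fs_i / 2 * 0.8, order = 4)
    delta <- filtfilt_keep_dc(aa, delta)[seq(1L, n, by = k)]
  }
  # stage 2: the 2nd-order low-pass that defines the EOD-frequency trace
  filt <- butter_lowpass(fs_i, lowpass_cutoff, order = 2)
  trace <- filtfilt_keep_dc(filt, delta)
  behavior_trace((seq_along(trace) - 1) / fs_i, trace, fs_i, lowpass_cutoff)
}

#' Behavioral gain at an envelope frequency
#'
#' Cycle-averages the EOD-frequency trace at the envelope frequency, fits a
#' sinewave, and divides the fitted modulation amplitude by the envelope
#' amplitude.  Because the 0.05 Hz extraction low-pass attenuates envelope
#' frequencies up to 1 Hz by a known Butterworth factor, the filter's
#' squared magnitude response at the envelope frequency is divided out by
#' default; set `correct_filter_gain = FALSE` for the raw (attenuated)
#' value.
#'
#' @param trace a [behavior_trace()].
#' @param envelope_frequency envelope frequency in Hz.
#' @param envelope_amplitude envelope amplitude in contrast units (> 0).
#' @param n_bins phase bins for the cycle average (default 32).
#' @param edge_trim seconds discarded at each end of the trace before
#'   folding (default: five filter time constants of the extraction
#'   low-pass, to clear filtfilt transients, which compete with the heavily
#'   attenuated high-frequency modulations).
#' @param correct_filter_gain divide out the extraction filter's gain at the
#'   envelope frequency (default `TRUE`).
#' @return gain in Hz per unit contrast.
#' @export
behavioral_gain <- function(trace, envelope_frequency, envelope_amplitude,
                            n_bins = 32, edge_trim = NULL,
                            correct_filter_gain = TRUE) {
  stopifnot(inherits(trace, "behavior_trace"))
  stop_if_not_scalar(envelope_frequency, "envelope_frequency")
  if (envelope_amplitude <= 0) {
    stop("`envelope_amplitude` must be positive", call. = FALSE)
  }
  if (is.null(edge_trim)) {
    edge_trim <- if (is.finite(trace$lowpass_cutoff)) {
      5 / (2 * pi * trace$lowpass_cutoff * 0.707)
    } else 0
  }
  t_total <- trace$time[length(trace$time)]
  t0 <- edge_trim
  t1 <- t_total - edge_trim
  n_cycles <- floor((t1 - t0) * envelope_frequency)
  if (n_cycles < 2) {
    stop("trace covers fewer than 2 complete envelope cycles after edge ",
         "trimming", call. = FALSE)
  }
  t_end <- t0 + n_cycles / envelope_frequency
  keep <- trace$time >= t0 & trace$time < t_end
  phase <- ((trace$time[keep] - t0) * envelope_frequency) %% 1
  bin <- pmin(floor(phase * n_bins) + 1L, n_bins)
  folded <- vapply(split(trace$eod_frequency[keep], bin), mean, numeric(1))
  centers <- (as.integer(names(folded)) - 0.5) / n_bins
  # least-squares sinewave fit at the occupied bin centers: when the trace
  # sampling is commensurate with the envelope period some bins stay empty,
  # and the uniform-bin Fourier projection would leak the large DC offset
  # into the fundamental
  co <- stats::lm.fit(cbind(1, sin(2 * pi * centers),
                            cos(2 * pi * centers)),
                      unname(folded))$coefficients
  gain <- sqrt(sum(co[2:3]^2)) / envelope_amplitude
  if (correct_filter_gain && is.finite(trace$lowpass_cutoff)) {
    filt <- butter_lowpass(trace$sample_rate, trace$lowpass_cutoff,
                           order = 2)
    gain <- gain / filtfilt_gain2(filt, envelope_frequency,
                                  trace$sample_rate)
  }
  gain
}
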