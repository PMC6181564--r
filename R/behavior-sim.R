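# Synthetic behavior: an electric-organ-discharge (EOD) signal whose
# instantaneous frequency tracks the stimulus envelope with a low-pass
# power-law behavioral gain.

#' Behavioral specification
#'
#' @param eod_base_frequency resting EOD frequency in Hz (default 800).
#' @param behavior_gain_coefficient Gb, frequency excursion per unit
#'   envelope contrast at 1 Hz envelope frequency (Hz per unit contrast).
#' @param behavior_gain_exponent beta_b, power-law exponent of the
#'   behavioral gain; negative values give the low-pass tracking seen in
#'   behaving fish.
#' @param seed integer RNG seed or `NULL` (the synthesis itself is
#'   deterministic; the seed is kept for forward compatibility).
#' @return an object of class `behavior_spec`.
#' @export
behavior_spec <- function(eod_base_frequency = 800,
                          behavior_gain_coefficient = 20,
                          behavior_gain_exponent = -0.5,
                          seed = NULL) {
  stop_if_not_scalar(eod_base_frequency, "eod_base_frequency")
  if (eod_base_frequency <= 0) {
    stop("`eod_base_frequency` must be positive", call. = FALSE)
  }
  structure(
    list(eod_base_frequency = eod_base_frequency,
         behavior_gain_coefficient = behavior_gain_coefficient,
         behavior_gain_exponent = behavior_gain_exponent, seed = seed),
    class = "behavior_spec")
}

#' Simulate an envelope-tracking EOD signal
#'
#' The instantaneous EOD frequency is the base frequency plus the
#' mean-subtracted envelope passed through the behavioral power-law transfer
#' function `Gb * f^beta_b`; the signal is `sin(2 pi phi(t))` with
#' phase-continuous `phi` obtained by integrating the instantaneous
#' frequency.
#'
#' @param stim a `stimulus_set` whose sample rate exceeds twice the peak
#'   instantaneous frequency.
#' @param spec a [behavior_spec()].
#' @return an object of class `eod_signal` with fields `time`, `signal`,
#'   `sample_rate`, and `instantaneous_frequency` (the programmed frequency
#'   trace, useful as a ground-truth oracle).
#' @export
simulate_behavior <- function(stim, spec) {
  stopifnot(inherits(stim, "stimulus_set"), inherits(spec, "behavior_spec"))
  fs <- stim$spec$sample_rate
  f_inst <- spec$eod_base_frequency +
    power_law_drive(stim$envelope - 1, fs, spec$behavior_gain_coefficient,
                    spec$behavior_gain_exponent)
  if (fs <= 2 * max(f_inst)) {
    stop(sprintf(
      "sample rate %g Hz must exceed twice the peak instantaneous EOD ",
      fs), "frequency", call. = FALSE)
  }
  if (any(f_inst <= 0)) {
    stop("instantaneous EOD frequency went non-positive; reduce the ",
         "behavioral gain", call. = FALSE)
  }
  phase <- cumsum(f_inst) / fs
  structure(
    list(time = stim$time, signal = sin(2 * pi * phase), sample_rate = fs,
         instantaneous_frequency = f_inst),
    class = "eod_signal")
}

#' @export
print.eod_signal <- function(x, ...) {
  cat(sprintf("<eod_signal> %d samples @ %g Hz, mean frequency %.1f Hz\n",
              length(x$signal), x$sample_rate,
              mean(x$instantaneous_frequency)))
  invisible(x)
}
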