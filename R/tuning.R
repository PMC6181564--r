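# Tuning curves, power-law fits, response-power prediction under natural
# stimulus statistics, the whitening index, and sensitivity changes.

#' Tuning curve container
#'
#' Per-envelope-frequency gain values for one unit under one condition.
#'
#' @param frequencies envelope frequencies in Hz, strictly ascending.
#' @param gains gains in Hz per unit contrast (>= 0), same length.
#' @param unit_id unit label.
#' @param condition condition label.
#' @return an object of class `tuning_curve`.
#' @export
tuning_curve <- function(frequencies, gains, unit_id = "unit",
                         condition = "custom") {
  stopifnot(is.numeric(frequencies), is.numeric(gains),
            length(frequencies) == length(gains))
  if (any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be strictly ascending", call. = FALSE)
  }
  if (any(gains < 0)) stop("`gains` must be >= 0", call. = FALSE)
  structure(
    list(frequencies = frequencies, gains = gains, unit_id = unit_id,
         condition = condition),
    class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s / %s\n", x$unit_id, x$condition))
  print(stats::setNames(round(x$gains, 3), paste0(x$frequencies, " Hz")))
  invisible(x)
}

#' Neural gain from a sinewave fit
#'
#' The firing-rate modulation amplitude divided by the stimulus envelope
#' amplitude, in Hz per unit contrast.
#'
#' @param fit a [fit_sinewave()] result.
#' @param envelope_amplitude envelope modulation amplitude in contrast units
#'   (> 0); for a sinusoidal envelope this is the modulation depth.
#' @return gain in Hz per unit contrast.
#' @export
compute_gain <- function(fit, envelope_amplitude) {
  stop_if_not_scalar(envelope_amplitude, "envelope_amplitude")
  if (envelope_amplitude <= 0) {
    stop("`envelope_amplitude` must be positive", call. = FALSE)
  }
  fit$amplitude / envelope_amplitude
}

#' Power-law fit to a tuning curve
#'
#' Ordinary least squares on (log10 frequency, log10 gain); the exponent is
#' the slope.  Zero gains cannot be log-transformed and are excluded with a
#' warning.
#'
#' @param curve a [tuning_curve()] (or any list with `frequencies` and
#'   `gains`).
#' @return an object of class `power_law_fit` with `exponent`,
#'   `log10_coefficient`, `r_squared`.
#' @export
fit_power_law <- function(curve) {
  f <- curve$frequencies
  g <- curve$gains
  pos <- g > 0
  if (any(!pos)) {
    warning(sprintf("%d zero gain value(s) excluded from the power-law fit",
                    sum(!pos)), call. = FALSE)
  }
  if (sum(pos) < 3) {
    stop("power-law fit needs at least 3 positive gain values",
         call. = FALSE)
  }
  x <- log10(f[pos])
  y <- log10(g[pos])
  co <- stats::coef(stats::lm(y ~ x))
  pred <- co[1] + co[2] * x
  sst <- sum((y - mean(y))^2)
  ssr <- sum((y - pred)^2)
  r2 <- if (sst < 1e-300) 1 else max(0, min(1, 1 - ssr / sst))
  structure(
    list(exponent = unname(co[2]), log10_coefficient = unname(co[1]),
         r_squared = r2),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> gain ~ %.3g * f^%.3f (r^2 = %.3f)\n",
              10^x$log10_coefficient, x$exponent, x$r_squared))
  invisible(x)
}

#' Predicted response power under natural stimulus statistics
#'
#' Squares the gain at each envelope frequency and multiplies it by the
#' power of the natural stimulus, `f^alpha` with `alpha = -0.8` by default
#' (normalized to 1 at 1 Hz; the whitening index is scale-invariant so the
#' normalization is cosmetic).
#'
#' @param curve a [tuning_curve()].
#' @param stimulus_exponent natural stimulus spectral exponent alpha
#'   (default -0.8).
#' @return an object of class `whitening_result` with `frequencies`,
#'   `response_power`, `white_index`, `stimulus_exponent`.
#' @export
predict_response_power <- function(curve, stimulus_exponent = -0.8) {
  f <- curve$frequencies
  power <- curve$gains^2 * f^stimulus_exponent
  structure(
    list(frequencies = f, response_power = power,
         white_index = white_index(f, power),
         stimulus_exponent = stimulus_exponent),
    class = "whitening_result")
}

#' @export
print.whitening_result <- function(x, ...) {
  cat(sprintf(
    "<whitening_result> alpha = %g, white index = %.3f\n",
    x$stimulus_exponent, x$white_index))
  invisible(x)
}

#' Whitening index
#'
#' Trapezoidal area under the response-power curve divided by the
#' trapezoidal area of the constant curve at the maximum power over the same
#' frequency range.  Ranges between 0 and 1; 1 indicates complete whitening
#' (a power spectrum independent of frequency).
#'
#' @param frequencies frequencies in Hz, ascending (>= 2 values).
#' @param response_power non-negative power values, not all zero.
#' @return the whitening index in `[0, 1]`.
#' @examples
#' white_index(envelope_frequency_set(), rep(3, 6))  # exactly 1
#' @export
white_index <- function(frequencies, response_power) {
  stopifnot(is.numeric(frequencies), is.numeric(response_power),
            length(frequencies) == length(response_power))
  if (length(frequencies) < 2) {
    stop("need at least 2 frequencies", call. = FALSE)
  }
  if (any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be strictly ascending", call. = FALSE)
  }
  if (any(response_power < 0)) {
    stop("`response_power` must be >= 0", call. = FALSE)
  }
  if (all(response_power == 0)) {
    stop("`response_power` is all zero", call. = FALSE)
  }
  trapezoid_area(frequencies, response_power) /
    trapezoid_area(frequencies,
                   rep(max(response_power), length(response_power)))
}

#' Relative sensitivity change between two conditions
#'
#' `100 * (gain_drug - gain_control) / gain_control`, the percent change in
#' gain after a manipulation; vectorized over paired gains.
#'
#' @param gain_drug gain(s) after the manipulation.
#' @param gain_control gain(s) under control conditions (> 0).
#' @return percent change(s).
#' @export
sensitivity_change <- function(gain_drug, gain_control) {
  stopifnot(is.numeric(gain_drug), is.numeric(gain_control))
  if (any(gain_control <= 0)) {
    stop("`gain_control` must be positive", call. = FALSE)
  }
  100 * (gain_drug - gain_control) / gain_control
}
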