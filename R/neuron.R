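# Synthetic envelope-tuned spiking neurons.  The model is deliberately
# simple: a rectified linear rate whose envelope-driven component passes
# through a power-law transfer function G0 * f^beta (the quantity the
# analysis pipeline is supposed to recover), plus a direct AM term that
# gives the spike-triggered average something to find.  Spikes are drawn as
# an inhomogeneous Poisson process by thinning.

#' Neuron specification
#'
#' @param baseline_rate spontaneous firing rate in Hz (>= 0).
#' @param gain_coefficient G0, envelope gain at 1 Hz in Hz per unit
#'   contrast (>= 0).
#' @param gain_exponent beta, the power-law tuning exponent: gain(f) =
#'   G0 * f^beta.  ~0.4 gives high-pass tuning, 0 gives flat tuning.
#' @param response_phase phase of the rate modulation relative to the
#'   envelope, radians (default 0).
#' @param am_sensitivity rate contribution per unit AM amplitude, Hz
#'   (controls STA magnitude; default 0).
#' @param refractory absolute refractory period in seconds (default 0).
#' @param seed integer RNG seed or `NULL`.
#' @param condition_label free-text condition tag.
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(baseline_rate,
                        gain_coefficient,
                        gain_exponent,
                        response_phase = 0,
                        am_sensitivity = 0,
                        refractory = 0,
                        seed = NULL,
                        condition_label = "custom") {
  stop_if_not_scalar(baseline_rate, "baseline_rate")
  stop_if_not_scalar(gain_coefficient, "gain_coefficient")
  stop_if_not_scalar(gain_exponent, "gain_exponent")
  if (baseline_rate < 0) stop("`baseline_rate` must be >= 0", call. = FALSE)
  if (gain_coefficient < 0) {
    stop("`gain_coefficient` must be >= 0", call. = FALSE)
  }
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  structure(
    list(baseline_rate = baseline_rate, gain_coefficient = gain_coefficient,
         gain_exponent = gain_exponent, response_phase = response_phase,
         am_sensitivity = am_sensitivity, refractory = refractory,
         seed = seed, condition_label = condition_label),
    class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat(sprintf(
    "<neuron_spec> %s | baseline %g Hz | G0 %g Hz/contrast | beta %g\n",
    x$condition_label, x$baseline_rate, x$gain_coefficient, x$gain_exponent))
  invisible(x)
}

#' Condition presets for the synthetic populations
#'
#' Fully populated [neuron_spec()]s encoding the qualitative tuning
#' structure of each experimental condition: hindbrain pyramidal cells under
#' control conditions and midbrain multipolar cells are high-pass (beta =
#' 0.4); complete feedback inactivation, indirect-feedback inactivation and
#' stellate cells are flat (beta = 0).  Complete inactivation scales the
#' gain coefficient down relative to control (attenuation at every
#' frequency); indirect-feedback inactivation scales it up (enhancement at
#' low frequencies).  The numeric values themselves are synthetic-population
#' choices, not measured constants; see the methods vignette.
#'
#' @param label one of `"control_ell"`, `"np_inactivated"`,
#'   `"pet_inactivated"`, `"stellate"`, `"multipolar"`, `"custom"`.
#' @param ... for `label = "custom"`, fields passed through unchanged to
#'   [neuron_spec()]; for presets, overrides of individual fields (e.g.
#'   `seed`).
#' @return a `neuron_spec`.
#' @examples
#' condition_preset("control_ell")$gain_exponent  # 0.4
#' condition_preset("np_inactivated")$gain_exponent  # 0
#' @export
condition_preset <- function(label, ...) {
  if (identical(label, "custom")) return(neuron_spec(...))
  presets <- list(
    control_ell = list(baseline_rate = 60, gain_coefficient = 220,
                       gain_exponent = 0.4, am_sensitivity = 2),
    np_inactivated = list(baseline_rate = 60, gain_coefficient = 44,
                          gain_exponent = 0, am_sensitivity = 2),
    pet_inactivated = list(baseline_rate = 60, gain_coefficient = 264,
                           gain_exponent = 0, am_sensitivity = 3),
    stellate = list(baseline_rate = 40, gain_coefficient = 150,
                    gain_exponent = 0, am_sensitivity = 2),
    multipolar = list(baseline_rate = 60, gain_coefficient = 250,
                      gain_exponent = 0.4, am_sensitivity = 2))
  if (!label %in% names(presets)) {
    stop(sprintf("unknown condition label \"%s\"; must be one of %s", label,
                 paste(c(names(presets), "custom"), collapse = ", ")),
         call. = FALSE)
  }
  args <- utils::modifyList(presets[[label]], list(...))
  args$condition_label <- label
  do.call(neuron_spec, args)
}

# Apply the power-law transfer function H(f) = G0 |f|^beta e^{i phase
# sign(f)} to a zero-mean drive signal in the frequency domain (zero-phase
# in amplitude terms; the DC component is zeroed).  For a sinusoidal drive
# of amplitude d at frequency f this returns amplitude G0 f^beta d, which is
# exactly the programmed gain structure the pipeline must recover.
power_law_drive <- function(dev, fs, g0, beta, phase = 0) {
  n <- length(dev)
  freq <- seq(0, n - 1) / n * fs
  freq[freq > fs / 2] <- freq[freq > fs / 2] - fs
  h <- complex(modulus = ifelse(freq == 0, 0, g0 * abs(freq)^beta),
               argument = phase * sign(freq))
  Re(stats::fft(stats::fft(dev) * h, inverse = TRUE)) / n
}

#' Instantaneous firing rate of a model neuron
#'
#' The rectified rate `max(0, baseline + envelope drive + am_sensitivity *
#' am(t))`, where the envelope drive is the mean-subtracted envelope passed
#' through the neuron's power-law transfer function.
#'
#' @param stim a `stimulus_set`.
#' @param neuron a [neuron_spec()].
#' @return numeric rate vector (Hz) on the stimulus time grid.
#' @export
neuron_rate <- function(stim, neuron) {
  stopifnot(inherits(stim, "stimulus_set"), inherits(neuron, "neuron_spec"))
  drive <- power_law_drive(stim$envelope - 1, stim$spec$sample_rate,
                           neuron$gain_coefficient, neuron$gain_exponent,
                           neuron$response_phase)
  pmax(0, neuron$baseline_rate + drive + neuron$am_sensitivity * stim$am)
}

#' Simulate a spiking response to a stimulus
#'
#' Draws spikes from the inhomogeneous Poisson process with rate
#' [neuron_rate()] by thinning (candidate spikes at the peak rate, accepted
#' with probability `rate(t)/max(rate)`, rate interpolated between samples),
#' then optionally enforces an absolute refractory period.  Reproducible
#' given `neuron$seed`.
#'
#' @param stim a `stimulus_set`.
#' @param neuron a [neuron_spec()].
#' @param dt_max guard on model validity: peak rates at or above `1/dt_max`
#'   (default 0.5 ms) are rejected.
#' @return a [spike_train()].
#' @export
simulate_neuron <- function(stim, neuron, dt_max = 5e-4) {
  stopifnot(inherits(stim, "stimulus_set"), inherits(neuron, "neuron_spec"))
  rate <- neuron_rate(stim, neuron)
  rmax <- max(rate)
  if (rmax >= 1 / dt_max) {
    stop(sprintf(
      "peak rate %.0f Hz reaches 1/dt = %.0f Hz: rate model invalid", rmax,
      1 / dt_max), call. = FALSE)
  }
  duration <- stim$spec$duration
  times <- with_local_seed(neuron$seed, {
    if (rmax <= 0) {
      numeric(0)
    } else {
      n_cand <- stats::rpois(1, rmax * duration)
      # unique(): the RNG's finite granularity can duplicate candidate
      # times in long simulations, and spike times must strictly increase
      t_cand <- unique(sort(stats::runif(n_cand, 0, duration)))
      r_cand <- stats::approx(stim$time, rate, t_cand, rule = 2)$y
      t_cand[stats::runif(length(t_cand)) < r_cand / rmax]
    }
  })
  if (neuron$refractory > 0 && length(times) > 1) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= neuron$refractory) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  spike_train(times, duration)
}
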