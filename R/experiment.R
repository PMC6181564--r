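# Population experiments: simulate units under paired (within-unit
# pre/post) or unpaired condition contrasts, run the full per-unit analysis
# chain, and aggregate with nonparametric statistics.

#' Trial duration policy per envelope frequency
#'
#' `"cycles20"` is `max(100 s, 20 cycles)`, adequate for single-unit
#' exploration.  `"power"` is `max(100 s, 250 * f^-0.8 s)`, which equalizes
#' the relative shot-noise error of the cycle-histogram gain estimate across
#' frequencies (the modulation amplitude scales as `f^0.4` for high-pass
#' units, so the required duration scales as `f^-0.8`); population
#' experiments default to it.  See the methods vignette for the power
#' analysis.
#'
#' @param envelope_frequency envelope frequency in Hz.
#' @param policy `"power"` or `"cycles20"`.
#' @return duration in seconds.
#' @export
duration_for_frequency <- function(envelope_frequency,
                                   policy = c("power", "cycles20")) {
  policy <- match.arg(policy)
  f <- envelope_frequency
  d <- switch(policy,
    cycles20 = max(100, 20 / f),
    power = max(100, ceiling(250 * f^(-0.8))))
  if (d * f < 10) {
    warning(sprintf("only %.1f envelope cycles at %g Hz: cycle averages ",
                    d * f, f), "will be unstable", call. = FALSE)
  }
  d
}

#' Experiment configuration
#'
#' @param condition_pairs list of length-2 character vectors
#'   `c(control_label, manipulation_label)`; labels as in
#'   [condition_preset()].
#' @param n_units units per condition (>= 1; paired designs reuse the same
#'   units across the pair).
#' @param envelope_frequencies envelope frequencies in Hz; must come from
#'   [envelope_frequency_set()].
#' @param duration_policy see [duration_for_frequency()].
#' @param sample_rate stimulus sampling rate in Hz (default 500; the AM band
#'   tops out at 15 Hz, so this is heavily oversampled already).
#' @param modulation_depth envelope depth (default 0.20).
#' @param alpha_natural natural-stimulus spectral exponent used for
#'   response-power prediction (default -0.8).
#' @param paired share the stimulus seed across the two conditions within a
#'   unit (within-unit pre/post design, analyzed with the signed-rank test);
#'   if `FALSE`, the two conditions get independent units (Kruskal-Wallis).
#' @param seed base integer seed; per-unit stimulus and neuron seeds are
#'   derived from it deterministically.
#' @param output_dir if non-`NULL`, result tables and a run log are written
#'   there by [run_experiment()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(condition_pairs = list(c("control_ell",
                                                       "np_inactivated")),
                              n_units = 8,
                              envelope_frequencies = envelope_frequency_set(),
                              duration_policy = c("power", "cycles20"),
                              sample_rate = 500,
                              modulation_depth = 0.2,
                              alpha_natural = -0.8,
                              paired = TRUE,
                              seed = 1,
                              output_dir = NULL) {
  duration_policy <- match.arg(duration_policy)
  if (!is.list(condition_pairs) ||
      !all(vapply(condition_pairs, length, integer(1)) == 2L)) {
    stop("`condition_pairs` must be a list of length-2 label pairs",
         call. = FALSE)
  }
  if (n_units < 1) stop("`n_units` must be >= 1", call. = FALSE)
  if (!all(envelope_frequencies %in% envelope_frequency_set())) {
    stop("`envelope_frequencies` must come from envelope_frequency_set()",
         call. = FALSE)
  }
  if (length(envelope_frequencies) < 3) {
    stop("need at least 3 envelope frequencies for the power-law fit",
         call. = FALSE)
  }
  structure(
    list(condition_pairs = condition_pairs, n_units = n_units,
         envelope_frequencies = sort(envelope_frequencies),
         duration_policy = duration_policy, sample_rate = sample_rate,
         modulation_depth = modulation_depth,
         alpha_natural = alpha_natural, paired = paired, seed = seed,
         output_dir = output_dir),
    class = "experiment_config")
}

#' Analyze one unit's response at one envelope frequency
#'
#' Cycle histogram (discarding the first envelope cycle), sinewave fit, and
#' gain.
#'
#' @param spikes a [spike_train()].
#' @param envelope_frequency envelope frequency in Hz.
#' @param envelope_amplitude envelope amplitude in contrast units.
#' @param n_bins phase bins (default 32).
#' @return list with `gain`, `fit`, `hist`.
#' @export
analyze_unit <- function(spikes, envelope_frequency, envelope_amplitude,
                         n_bins = 32) {
  hist <- cycle_histogram(spikes, envelope_frequency, n_bins = n_bins,
                          t_start = 1 / envelope_frequency)
  fit <- fit_sinewave(hist)
  list(gain = compute_gain(fit, envelope_amplitude), fit = fit, hist = hist)
}

# Simulate + analyze every unit x frequency for one condition label.
# stim_seeds: matrix [unit, freq] of stimulus seeds.
simulate_condition <- function(label, config, stim_seeds, neuron_seed_salt) {
  freqs <- config$envelope_frequencies
  rows <- vector("list", config$n_units * length(freqs))
  k <- 0L
  for (u in seq_len(config$n_units)) {
    for (j in seq_along(freqs)) {
      f <- freqs[j]
      dur <- duration_for_frequency(f, config$duration_policy)
      sspec <- stimulus_spec(duration = dur,
                             sample_rate = config$sample_rate,
                             envelope_kind = "sinusoidal",
                             envelope_frequency = f,
                             modulation_depth = config$modulation_depth,
                             seed = stim_seeds[u, j])
      stim <- make_stimulus(sspec)
      nspec <- condition_preset(
        label, seed = derive_seed(config$seed, neuron_seed_salt, u, j))
      spikes <- simulate_neuron(stim, nspec)
      res <- analyze_unit(spikes, f, config$modulation_depth)
      k <- k + 1L
      rows[[k]] <- data.frame(
        unit = u, condition = label, frequency = f, gain = res$gain,
        rate_offset = res$fit$offset, n_spikes = length(spikes$times),
        duration = dur)
    }
  }
  do.call(rbind, rows)
}

summarize_units <- function(gains_df, alpha) {
  out <- lapply(split(gains_df, gains_df[c("unit", "condition")], drop = TRUE),
                function(d) {
    d <- d[order(d$frequency), ]
    curve <- tuning_curve(d$frequency, d$gain, unit_id = d$unit[1],
                          condition = d$condition[1])
    pl <- fit_power_law(curve)
    wr <- predict_response_power(curve, stimulus_exponent = alpha)
    data.frame(unit = d$unit[1], condition = d$condition[1],
               exponent = pl$exponent,
               log10_coefficient = pl$log10_coefficient,
               r_squared = pl$r_squared, white_index = wr$white_index)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$unit), ]
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare two conditions on a synthetic population
#'
#' Simulates `n_units` units under a control and a manipulation condition,
#' runs the full analysis chain per unit and envelope frequency (cycle
#' histogram, sinewave fit, gain, power-law fit, response-power prediction,
#' whitening index), computes per-unit sensitivity changes, and applies the
#' signed-rank test (paired) or Kruskal-Wallis (unpaired) to exponents and
#' white indices.  In the paired design the stimulus seed is shared across
#' conditions within a unit, mirroring within-cell pre/post recordings;
#' neuron noise seeds always differ.
#'
#' @param config an [experiment_config()] (its first condition pair is
#'   ignored here).
#' @param control,manipulation condition labels.
#' @return an object of class `comparison_result` with data frames `gains`,
#'   `units`, `population`, `sensitivity`, `tests`.
#' @export
compare_conditions <- function(config, control, manipulation) {
  stopifnot(inherits(config, "experiment_config"))
  freqs <- config$envelope_frequencies
  nu <- config$n_units
  mk_seeds <- function(salt) {
    matrix(vapply(seq_along(freqs),
                  function(j) vapply(seq_len(nu),
                                     function(u) derive_seed(config$seed,
                                                             salt, u, j),
                                     integer(1)),
                  integer(nu)),
           nrow = nu)
  }
  if (config$paired) {
    shared <- mk_seeds(1L)
    g1 <- simulate_condition(control, config, shared, 100L)
    g2 <- simulate_condition(manipulation, config, shared, 200L)
  } else {
    g1 <- simulate_condition(control, config, mk_seeds(1L), 100L)
    g2 <- simulate_condition(manipulation, config, mk_seeds(2L), 200L)
  }
  gains <- rbind(g1, g2)
  units <- summarize_units(gains, config$alpha_natural)

  # per-unit, per-frequency percent sensitivity change (paired design only)
  sensitivity <- NULL
  if (config$paired) {
    wide <- merge(g1[c("unit", "frequency", "gain")],
                  g2[c("unit", "frequency", "gain")],
                  by = c("unit", "frequency"),
                  suffixes = c("_control", "_manipulation"))
    wide$percent_change <- sensitivity_change(wide$gain_manipulation,
                                              wide$gain_control)
    sensitivity <- wide[order(wide$unit, wide$frequency), ]
    rownames(sensitivity) <- NULL
  }

  population <- do.call(rbind, lapply(split(units, units$condition),
                                      function(d) {
    data.frame(condition = d$condition[1], n_units = nrow(d),
               mean_exponent = mean(d$exponent),
               sem_exponent = sem(d$exponent),
               mean_white_index = mean(d$white_index),
               sem_white_index = sem(d$white_index))
  }))
  rownames(population) <- NULL

  tests <- NULL
  if (nu >= 3) {
    e1 <- units$exponent[units$condition == control]
    e2 <- units$exponent[units$condition == manipulation]
    w1 <- units$white_index[units$condition == control]
    w2 <- units$white_index[units$condition == manipulation]
    if (config$paired) {
      te <- wilcoxon_signed_rank(e1, e2)
      tw <- wilcoxon_signed_rank(w1, w2)
      ts <- wilcoxon_signed_rank(
        tapply(sensitivity$percent_change, sensitivity$unit, mean))
      tests <- data.frame(
        measure = c("exponent", "white_index", "sensitivity_change"),
        test = "wilcoxon_signed_rank",
        statistic = c(te$statistic, tw$statistic, ts$statistic),
        p_value = c(te$p_value, tw$p_value, ts$p_value))
    } else {
      te <- kruskal_wallis(list(e1, e2))
      tw <- kruskal_wallis(list(w1, w2))
      tests <- data.frame(
        measure = c("exponent", "white_index"), test = "kruskal_wallis",
        statistic = c(te$statistic, tw$statistic),
        p_value = c(te$p_value, tw$p_value))
    }
  } else {
    warning("fewer than 3 units: population p-values not computed",
            call. = FALSE)
  }

  structure(
    list(control = control, manipulation = manipulation, gains = gains,
         units = units, population = population, sensitivity = sensitivity,
         tests = tests, paired = config$paired, config = config),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s (%s, n = %d)\n", x$control,
              x$manipulation, if (x$paired) "paired" else "unpaired",
              x$config$n_units))
  print(x$population, row.names = FALSE)
  if (!is.null(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Run a configured experiment
#'
#' Runs [compare_conditions()] for every condition pair in the
#' configuration, optionally writing tidy CSV tables, a JSON summary, and a
#' plain-text log (seeds, versions) to `config$output_dir`.
#'
#' @param config an [experiment_config()].
#' @return a named list of `comparison_result`, one per condition pair.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  results <- list()
  for (pair in config$condition_pairs) {
    nm <- paste(pair, collapse = "_vs_")
    results[[nm]] <- compare_conditions(config, pair[1], pair[2])
  }
  if (!is.null(config$output_dir)) {
    write_experiment_results(results, config)
  }
  results
}
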