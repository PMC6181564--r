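# Plain-text interchange: stimuli and traces as two-column CSV with a JSON
# sidecar carrying the specification; spike trains as one-column text.

spec_to_list <- function(spec) spec[!vapply(spec, is.null, logical(1))]

#' Write / read a stimulus set
#'
#' `write_stimulus()` writes `<prefix>_am.csv` and `<prefix>_envelope.csv`
#' (columns `time_s`, `value`) plus `<prefix>_spec.json`;
#' `read_stimulus()` reconstructs the `stimulus_set`.
#'
#' @param stim a `stimulus_set`.
#' @param prefix file path prefix.
#' @return `write_stimulus()`: the prefix, invisibly; `read_stimulus()`: a
#'   `stimulus_set`.
#' @export
write_stimulus <- function(stim, prefix) {
  stopifnot(inherits(stim, "stimulus_set"))
  utils::write.csv(data.frame(time_s = stim$time, value = stim$am),
                   paste0(prefix, "_am.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = stim$time, value = stim$envelope),
                   paste0(prefix, "_envelope.csv"), row.names = FALSE)
  jsonlite::write_json(spec_to_list(unclass(stim$spec)),
                       paste0(prefix, "_spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(prefix) {
  am <- utils::read.csv(paste0(prefix, "_am.csv"))
  env <- utils::read.csv(paste0(prefix, "_envelope.csv"))
  js <- jsonlite::read_json(paste0(prefix, "_spec.json"),
                            simplifyVector = TRUE)
  spec <- do.call(stimulus_spec, js[c("duration", "sample_rate", "am_band",
                                      "am_filter_order", "envelope_kind",
                                      "envelope_frequency",
                                      "modulation_depth", "natural_exponent",
                                      "seed")])
  structure(list(time = am$time_s, am = am$value, envelope = env$value,
                 spec = spec),
            class = "stimulus_set")
}

#' Write / read a spike train
#'
#' One spike time (seconds, ascending) per line, plus a JSON sidecar with
#' the recording duration.
#'
#' @param spikes a [spike_train()].
#' @param prefix file path prefix (writes `<prefix>.txt` and
#'   `<prefix>.json`).
#' @return `write_spike_train()`: the prefix, invisibly;
#'   `read_spike_train()`: a [spike_train()].
#' @export
write_spike_train <- function(spikes, prefix) {
  stopifnot(inherits(spikes, "spike_train"))
  writeLines(format(spikes$times, digits = 17, scientific = FALSE,
                    trim = TRUE),
             paste0(prefix, ".txt"))
  jsonlite::write_json(list(duration = spikes$duration),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(prefix) {
  lines <- readLines(paste0(prefix, ".txt"))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  times <- if (length(lines)) as.numeric(lines) else numeric(0)
  spike_train(times, js$duration)
}

#' Write / read a behavior trace
#'
#' CSV with columns `time_s`, `eod_frequency_hz` plus a JSON sidecar with
#' the sampling rate and extraction cutoff.
#'
#' @param trace a [behavior_trace()].
#' @param prefix file path prefix.
#' @return `write_behavior_trace()`: the prefix, invisibly;
#'   `read_behavior_trace()`: a [behavior_trace()].
#' @export
write_behavior_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "behavior_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              eod_frequency_hz = trace$eod_frequency),
                   paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(sample_rate = trace$sample_rate,
                            lowpass_cutoff = trace$lowpass_cutoff),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_behavior_trace
#' @export
read_behavior_trace <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, ".csv"))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  behavior_trace(d$time_s, d$eod_frequency_hz, js$sample_rate,
                 js$lowpass_cutoff)
}

#' Write experiment results to disk
#'
#' Tidy CSV tables (`gains.csv`, `units.csv`, `population.csv`,
#' `sensitivity.csv`, `tests.csv` per condition pair), a JSON summary, and a
#' plain-text run log with seed and version stamps.
#'
#' @param results named list of `comparison_result` from
#'   [run_experiment()].
#' @param config the [experiment_config()] used.
#' @return the output directory, invisibly.
#' @export
write_experiment_results <- function(results, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    sub <- file.path(dir, nm)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$gains, file.path(sub, "gains.csv"),
                     row.names = FALSE)
    utils::write.csv(res$units, file.path(sub, "units.csv"),
                     row.names = FALSE)
    utils::write.csv(res$population, file.path(sub, "population.csv"),
                     row.names = FALSE)
    if (!is.null(res$sensitivity)) {
      utils::write.csv(res$sensitivity, file.path(sub, "sensitivity.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$tests)) {
      utils::write.csv(res$tests, file.path(sub, "tests.csv"),
                       row.names = FALSE)
    }
    summary[[nm]] <- list(population = res$population, tests = res$tests)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(c(
    sprintf("run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("envwhiten version: %s",
            as.character(utils::packageVersion("envwhiten"))),
    sprintf("R version: %s", R.version.string),
    sprintf("base seed: %d", config$seed),
    sprintf("n_units: %d", config$n_units),
    sprintf("duration policy: %s", config$duration_policy),
    sprintf("envelope frequencies: %s",
            paste(config$envelope_frequencies, collapse = ", "))),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
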