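# Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so generators are byte-reproducible without clobbering the global
#' random stream.  A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic derived seeds for multi-unit experiments; kept below 2^31.
derive_seed <- function(base, ...) {
  idx <- c(...)
  primes <- c(7919L, 104729L, 1299709L, 15485863L)
  s <- as.double(base)
  for (i in seq_along(idx)) {
    s <- s + as.double(idx[i]) * primes[((i - 1L) %% length(primes)) + 1L]
  }
  as.integer(s %% 2147483629)
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector (the signal plus i
#' times its Hilbert transform), computed by zeroing negative frequencies of
#' the FFT.  `Mod(analytic_signal(x))` is the instantaneous amplitude
#' envelope used for modulation-depth readout.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase (forward-backward) Butterworth wrappers.  Filtering is always
# zero-phase in this package so that amplitude estimates and STA lag
# structure are not biased by filter delay.

butter_bandpass <- function(fs, low, high, order = 4) {
  stopifnot(fs > 2 * high, low > 0, high > low)
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

butter_lowpass <- function(fs, cutoff, order = 2) {
  stopifnot(cutoff > 0, fs > 2 * cutoff)
  signal::butter(order, cutoff / (fs / 2), type = "low")
}

butter_highpass <- function(fs, cutoff, order = 8) {
  stopifnot(cutoff > 0, fs > 2 * cutoff)
  signal::butter(order, cutoff / (fs / 2), type = "high")
}

filtfilt_keep_dc <- function(filt, x) {
  # Remove the mean before forward-backward filtering and restore it after:
  # low-pass edge transients scale with the DC step at the boundaries, and
  # rate traces have large means relative to their modulation.
  m <- mean(x)
  signal::filtfilt(filt, x - m) + m
}

# Squared magnitude response of a forward-backward filter at frequency f (Hz)
# for a filter designed at sampling rate fs.  filtfilt applies |H|^2.
filtfilt_gain2 <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  h <- signal::polyval(rev(filt$b), z) / signal::polyval(rev(filt$a), z)
  Mod(h)^2
}

# trapezoid area wrapper (kept in one place so the whitening index and its
# tests share the same quadrature)
trapezoid_area <- function(x, y) pracma::trapz(x, y)

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
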