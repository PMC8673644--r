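# Shared small helpers: dB conversions, seeded evaluation, argument checks.

#' Decibel conversions for pressure amplitudes
#'
#' `db_to_amp()` maps a level in dB re 1 uPa to a linear pressure amplitude;
#' `amp_to_db()` is its inverse. Peak-to-peak received levels use the same
#' 20 log10 convention applied to the max-minus-min pressure.
#'
#' @param db level in dB re 1 uPa.
#' @param amp linear amplitude in uPa (must be positive for a finite result).
#' @return numeric vector of the same length.
#' @export
db_to_amp <- function(db) 10^(db / 20)

#' @rdname db_to_amp
#' @export
amp_to_db <- function(amp) 20 * log10(amp)

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL runs in the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one integer seed, keeping them within
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be positive", name)
  invisible(x)
}

# Hann window (periodic form not needed; symmetric is standard for PSDs).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# Envelope of a real signal as the magnitude of its analytic signal,
# computed by the FFT method. For streaming use, callers pass a padded
# segment and discard the pad, since the FFT method is circular.
#' Signal envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal of a real vector, computed in the
#' frequency domain. This is the envelope estimator used by the detector for
#' threshold crossing and duration measurement.
#'
#' @param x real numeric vector.
#' @return nonnegative numeric vector of the same length.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
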