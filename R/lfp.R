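#' Uniformly sampled time series
#'
#' Light container for a regularly sampled signal: raw or filtered LFP,
#' amplitude envelopes, instantaneous phase. Values are stored as a plain
#' numeric vector together with the sampling rate, so downstream functions
#' never have to guess the time base.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param t0 time of the first sample in seconds (default 0).
#' @param units unit label carried along for display ("uV" for raw LFP,
#'   "rad" for phase series, ...).
#'
#' @return An object of class `"lfp"`: a list with elements `values`, `fs`,
#'   `t0`, `units`.
#' @examples
#' x <- lfp(sin(2 * pi * 6 * seq(0, 1, by = 1e-3)), fs = 1000)
#' head(lfp_times(x))
#' @export
lfp <- function(values, fs, t0 = 0, units = "uV") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 t0 = as.numeric(t0), units = units),
            class = "lfp")
}

#' @export
print.lfp <- function(x, ...) {
  cat(sprintf("<lfp> %d samples @ %g Hz (%.3f s), units: %s\n",
              length(x$values), x$fs, length(x$values) / x$fs, x$units))
  invisible(x)
}

#' Sample times of a time series
#'
#' @param x an [lfp] object.
#' @return Numeric vector of sample times in seconds.
#' @export
lfp_times <- function(x) {
  stopifnot(inherits(x, "lfp"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a time series in seconds
#' @param x an [lfp] object.
#' @export
lfp_duration <- function(x) {
  stopifnot(inherits(x, "lfp"))
  length(x$values) / x$fs
}

#' Stimulation event train
#'
#' Strictly increasing event times in seconds, e.g. TTL pulse instants or
#' ground-truth extrema.
#'
#' @param times numeric vector of event times (seconds), strictly increasing.
#' @param mode label for how the train was produced (`"peak"`, `"trough"`,
#'   `"fixed"`, ...).
#' @param config optional list of scheduler settings, stored for provenance.
#' @return An object of class `"event_train"`.
#' @export
event_train <- function(times, mode = "unspecified", config = list()) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("event times must not contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  structure(list(times = times, mode = mode, config = config),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events, mode '%s'", length(x$times), x$mode))
  if (length(x$times))
    cat(sprintf(", span %.3f-%.3f s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$times)

## ---- phase utilities -------------------------------------------------------

#' Wrap phase angles to (-pi, pi]
#'
#' The package-wide phase convention: the theta peak sits at phase 0 and the
#' trough at +/- pi, with angles wrapped to the half-open interval (-pi, pi].
#'
#' @param x numeric vector of angles in radians.
#' @return Wrapped angles in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps so the phase grows (approximately) monotonically,
#' which gives every theta cycle a distinct phase coordinate.
#'
#' @param p numeric vector of wrapped phase angles (radians).
#' @return Unwrapped phase vector.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal `x + i H(x)`; its argument is the
#' instantaneous phase and its modulus the instantaneous amplitude.
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for the analytic-signal construction")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Circular mean of angles
#'
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @return Mean direction in (-pi, pi], or `NA` if the resultant vector has
#'   (near-)zero length, i.e. the direction is undefined.
#' @export
circular_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  z <- sum(w * exp(1i * theta))
  if (Mod(z) / max(sum(abs(w)), .Machine$double.eps) < 1e-10) return(NA_real_)
  wrap_phase(Arg(z))
}

#' Circular correlation of two angle series
#'
#' Fisher-Lee T-linear circular association, computed from pairwise angle
#' differences (`sum sin(a_i - a_j) sin(b_i - b_j)` over pairs, normalized).
#' Unlike mean-direction formulations it remains stable when the marginal
#' phase distributions are uniform, the usual case when comparing estimated
#' instantaneous phase against ground truth over whole sessions.
#'
#' @param a,b angle vectors in radians, equal length.
#' @param max_n series longer than this are thinned to `max_n` evenly spaced
#'   points before forming the O(n^2) pair set.
#' @return Correlation in \[-1, 1\].
#' @export
circular_correlation <- function(a, b, max_n = 2000) {
  stopifnot(length(a) == length(b))
  if (length(a) > max_n) {
    idx <- round(seq(1, length(a), length.out = max_n))
    a <- a[idx]
    b <- b[idx]
  }
  sa <- sin(outer(a, a, "-"))
  sb <- sin(outer(b, b, "-"))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}
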