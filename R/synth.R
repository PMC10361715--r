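#' Parameters of the synthetic LFP generator
#'
#' Bundles every knob of the ground-truth-known LFP simulator: a
#' quasi-periodic theta oscillation whose cycle frequencies are drawn from a
#' truncated Gaussian (phase-continuous across cycle boundaries), a 1/f^alpha
#' Gaussian background, and optionally a theta-phase-modulated gamma
#' component for coupling analyses.
#'
#' Defaults emulate a CA1 recording at 1 kHz: theta cycles with mean 7 Hz,
#' SD 1 Hz, truncated to the 4-10 Hz theta band; 100 uV theta amplitude over
#' 22.4 uV broadband 1/f noise (~10 dB signal-to-noise); mid-gamma carrier
#' at 70 Hz (55-85 Hz band) whose amplitude is maximal at the theta trough.
#'
#' @param duration session length in seconds.
#' @param fs sampling rate in Hz.
#' @param theta_freq_mean,theta_freq_sd mean and SD (Hz) of the per-cycle
#'   frequency distribution before truncation.
#' @param theta_freq_bounds length-2 truncation bounds in Hz (theta band).
#' @param theta_amp theta amplitude in microvolts.
#' @param noise_exponent alpha of the 1/f^alpha background spectrum.
#' @param noise_scale standard deviation of the background noise (uV); 0
#'   disables the noise.
#' @param gamma_center,gamma_bandwidth center frequency and bandwidth (Hz)
#'   of the gamma component used by [generate_pac_lfp()].
#' @param gamma_amp gamma base amplitude in microvolts.
#' @param coupling_strength modulation depth of the gamma envelope by theta
#'   phase, in \[0, 1\]; 0 means no coupling.
#' @param coupling_phase theta phase (radians, peak = 0) at which the gamma
#'   envelope is maximal; pi places gamma bursts at the trough.
#' @param gamma_carrier `"noise"` for a narrowband filtered-noise carrier
#'   (realistic envelope statistics) or `"sine"` for a pure tone.
#' @param seed integer RNG seed; identical parameters and seed reproduce the
#'   session bit-for-bit.
#' @return A validated list of class `"synth_params"`.
#' @export
synth_params <- function(duration = 180, fs = 1000,
                         theta_freq_mean = 7, theta_freq_sd = 1,
                         theta_freq_bounds = c(4, 10),
                         theta_amp = 100,
                         noise_exponent = 1, noise_scale = 22.4,
                         gamma_center = 70, gamma_bandwidth = 20,
                         gamma_amp = 20,
                         coupling_strength = 0, coupling_phase = pi,
                         gamma_carrier = c("noise", "sine"),
                         seed = 1L) {
  gamma_carrier <- match.arg(gamma_carrier)
  p <- list(duration = duration, fs = fs,
            theta_freq_mean = theta_freq_mean, theta_freq_sd = theta_freq_sd,
            theta_freq_bounds = as.numeric(theta_freq_bounds),
            theta_amp = theta_amp,
            noise_exponent = noise_exponent, noise_scale = noise_scale,
            gamma_center = gamma_center, gamma_bandwidth = gamma_bandwidth,
            gamma_amp = gamma_amp,
            coupling_strength = coupling_strength,
            coupling_phase = coupling_phase,
            gamma_carrier = gamma_carrier,
            seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  chk(is.numeric(p$duration) && p$duration > 0, "duration", "must be > 0 s")
  chk(is.numeric(p$fs) && p$fs > 0, "fs", "must be a positive rate in Hz")
  chk(p$fs > 2 * (p$gamma_center + p$gamma_bandwidth / 2), "fs",
      "must exceed twice the top of the gamma band (Nyquist)")
  chk(length(p$theta_freq_bounds) == 2L &&
        p$theta_freq_bounds[1] < p$theta_freq_bounds[2],
      "theta_freq_bounds", "must be an increasing (low, high) pair in Hz")
  chk(p$theta_freq_bounds[1] < p$theta_freq_mean &&
        p$theta_freq_mean < p$theta_freq_bounds[2],
      "theta_freq_mean", "must lie strictly inside `theta_freq_bounds`")
  chk(p$theta_freq_sd >= 0, "theta_freq_sd", "must be >= 0")
  chk(p$theta_amp >= 0, "theta_amp", "must be >= 0")
  chk(p$noise_scale >= 0, "noise_scale", "must be >= 0")
  chk(p$coupling_strength >= 0 && p$coupling_strength <= 1,
      "coupling_strength", "must be in [0, 1]")
  chk(p$gamma_bandwidth > 0, "gamma_bandwidth", "must be > 0")
  invisible(p)
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_params> %.0f s @ %g Hz | theta %g Hz (sd %g, bounds %g-%g), ",
    "amp %g uV | 1/f^%g noise sd %g uV | gamma %g+/-%g Hz, coupling %g @ %.2f rad | seed %d\n"),
    x$duration, x$fs, x$theta_freq_mean, x$theta_freq_sd,
    x$theta_freq_bounds[1], x$theta_freq_bounds[2], x$theta_amp,
    x$noise_exponent, x$noise_scale, x$gamma_center, x$gamma_bandwidth / 2,
    x$coupling_strength, x$coupling_phase, x$seed))
  invisible(x)
}

## truncated-Gaussian draw by rejection; degenerate sd = 0 returns the mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

## spectrally shaped Gaussian noise with amplitude ~ f^(-alpha/2),
## rescaled to exactly the requested standard deviation
one_over_f_noise <- function(n, fs, alpha, scale) {
  if (scale <= 0) return(numeric(n))
  w <- rnorm(n)
  if (alpha == 0) return(scale * w / sd(w))
  f <- seq(0, n - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to physical frequencies
  shape <- c(0, f[-1]^(-alpha / 2))     # kill DC
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  scale * x / sd(x)
}

## shared theta core: cycle frequencies, piecewise-linear phase, ground truth
theta_core <- function(p) {
  n <- round(p$duration * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  ## draw cycles until they cover the session (plus one spare)
  freqs <- numeric(0)
  while (sum(1 / freqs) < p$duration) {
    need <- ceiling((p$duration - sum(1 / freqs)) * p$theta_freq_mean) + 5L
    freqs <- c(freqs, rtruncnorm(need, p$theta_freq_mean, p$theta_freq_sd,
                                 p$theta_freq_bounds[1], p$theta_freq_bounds[2]))
  }
  bounds <- c(0, cumsum(1 / freqs))
  idx <- findInterval(t, bounds)
  phi <- 2 * pi * (idx - 1) + 2 * pi * freqs[idx] * (t - bounds[idx])
  started <- bounds[-length(bounds)] < p$duration
  peak_times <- bounds[-length(bounds)][started]
  trough_times <- (bounds[-length(bounds)] + 0.5 / freqs)[started]
  trough_times <- trough_times[trough_times < p$duration]
  truth <- structure(
    list(peak_times = peak_times,
         trough_times = trough_times,
         instantaneous_phase = lfp(wrap_phase(phi), p$fs, units = "rad"),
         cycle_frequencies = freqs[started]),
    class = "theta_truth")
  list(t = t, phi = phi, truth = truth, n = n)
}

#' @export
print.theta_truth <- function(x, ...) {
  cat(sprintf("<theta_truth> %d peaks, %d troughs, mean cycle freq %.2f Hz\n",
              length(x$peak_times), length(x$trough_times),
              mean(x$cycle_frequencies)))
  invisible(x)
}

#' Generate a quasi-periodic theta LFP with known ground truth
#'
#' The theta component is a per-cycle sinusoid: each cycle's frequency is an
#' independent draw from a truncated Gaussian and the phase advances
#' continuously across cycle boundaries (2*pi per cycle, starting at phase 0,
#' i.e. a peak at t = 0). Spectrally shaped 1/f^alpha Gaussian noise is added
#' on top. The returned ground truth holds the analytic peak/trough times and
#' wrapped instantaneous phase of the noiseless theta component, plus the
#' per-cycle frequencies.
#'
#' @param params a [synth_params] object.
#' @return A list with elements `signal` (an [lfp]) and `truth` (a
#'   `"theta_truth"` object with `peak_times`, `trough_times`,
#'   `instantaneous_phase`, `cycle_frequencies`).
#' @examples
#' s <- generate_theta_lfp(synth_params(duration = 2, seed = 42))
#' s$signal
#' head(s$truth$peak_times)
#' @export
generate_theta_lfp <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  validate_synth_params(params)
  set.seed(params$seed)
  core <- theta_core(params)
  x <- params$theta_amp * cos(core$phi) +
    one_over_f_noise(core$n, params$fs, params$noise_exponent,
                     params$noise_scale)
  list(signal = lfp(x, params$fs), truth = core$truth)
}

#' Generate a theta LFP with phase-amplitude-coupled gamma
#'
#' Adds to the theta-plus-noise signal of [generate_theta_lfp()] a narrowband
#' gamma component whose instantaneous amplitude is
#' `gamma_amp * (1 + coupling_strength * cos(theta_phase - coupling_phase))`,
#' i.e. theta-nested gamma bursts at a controllable preferred phase and
#' depth. The carrier is band-limited filtered noise by default (realistic
#' envelope statistics for modulation-index estimation) or a pure tone.
#'
#' @inheritParams generate_theta_lfp
#' @return As [generate_theta_lfp()]; the ground truth describes the theta
#'   component.
#' @examples
#' s <- generate_pac_lfp(synth_params(duration = 2, coupling_strength = 0.8,
#'                                    seed = 7))
#' @export
generate_pac_lfp <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  validate_synth_params(params)
  set.seed(params$seed)
  core <- theta_core(params)
  theta <- params$theta_amp * cos(core$phi)
  noise <- one_over_f_noise(core$n, params$fs, params$noise_exponent,
                            params$noise_scale)
  envelope <- params$gamma_amp *
    (1 + params$coupling_strength * cos(core$phi - params$coupling_phase))
  if (params$gamma_carrier == "sine") {
    carrier <- cos(2 * pi * params$gamma_center * core$t)
  } else {
    band <- params$gamma_center + c(-0.5, 0.5) * params$gamma_bandwidth
    bf <- signal::butter(4, band / (params$fs / 2), type = "pass")
    carrier <- signal::filtfilt(bf, rnorm(core$n))
    carrier <- carrier / sd(carrier)
  }
  list(signal = lfp(theta + envelope * carrier + noise, params$fs),
       truth = core$truth)
}

#' Generate a synthetic motion trace with known freezing bouts
#'
#' Stands in for the per-frame motion output of video tracking: motion values
#' sit above the stillness threshold except during the requested bouts, where
#' they drop below it (both jittered). The generating bout list and threshold
#' are embedded so downstream freezing scoring can be checked exactly.
#'
#' @param design an [epoch_design] fixing the trial duration.
#' @param bouts list of `c(start, duration)` pairs in seconds (or a 2-column
#'   matrix); bouts must be non-overlapping and inside the trial.
#' @param fps frame rate in Hz (default 30).
#' @param threshold stillness threshold on the motion scale; embedded in the
#'   returned object.
#' @param seed integer RNG seed.
#' @return An object of class `"motion_trace"`: `values`, `fps`, `threshold`,
#'   `bouts` (2-column matrix, seconds), `design`.
#' @examples
#' tr <- generate_motion_trace(epoch_design("Stim", 60),
#'                             bouts = list(c(10, 7)), seed = 1)
#' @export
generate_motion_trace <- function(design, bouts = list(), fps = 30,
                                  threshold = 1, seed = 1L) {
  stopifnot(inherits(design, "epoch_design"))
  if (fps <= 0) stop("`fps` must be positive")
  b <- if (is.matrix(bouts)) bouts else
    do.call(rbind, lapply(bouts, function(x) as.numeric(x[1:2])))
  if (is.null(b)) b <- matrix(numeric(0), ncol = 2)
  colnames(b) <- c("start", "duration")
  if (nrow(b)) {
    if (any(b[, 1] < 0) || any(b[, 1] + b[, 2] > design$total))
      stop("bouts must lie inside the trial duration")
    o <- order(b[, 1])
    b <- b[o, , drop = FALSE]
    if (nrow(b) > 1 && any(b[-nrow(b), 1] + b[-nrow(b), 2] > b[-1, 1]))
      stop("bouts must not overlap")
  }
  set.seed(as.integer(seed))
  n <- round(design$total * fps)
  tf <- (seq_len(n) - 1) / fps
  values <- threshold * (1.5 + 0.5 * runif(n))          # moving baseline
  for (r in seq_len(nrow(b))) {
    inb <- tf >= b[r, 1] & tf < b[r, 1] + b[r, 2]
    values[inb] <- threshold * (0.2 + 0.4 * runif(sum(inb)))
  }
  structure(list(values = values, fps = fps, threshold = threshold,
                 bouts = b, design = design),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames @ %g fps, %d ground-truth bouts\n",
              length(x$values), x$fps, nrow(x$bouts)))
  invisible(x)
}
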