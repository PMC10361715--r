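#' LFP preprocessing for spectral analysis
#'
#' Mean subtraction, 1-100 Hz fourth-order Butterworth bandpass, and a
#' fourth-order band-stop notch centered at 60 Hz to remove line noise.
#' All filtering is zero-phase (forward-backward).
#'
#' @param series an [lfp]; sampling rate must exceed 200 Hz.
#' @param band bandpass (low, high) in Hz.
#' @param notch notch center frequency in Hz; `NULL` disables it.
#' @param notch_halfwidth half-width of the band-stop in Hz (default 2).
#' @param order Butterworth order for both stages.
#' @return Preprocessed [lfp].
#' @export
preprocess_lfp <- function(series, band = c(1, 100), notch = 60,
                           notch_halfwidth = 2, order = 4) {
  stopifnot(inherits(series, "lfp"))
  fs <- series$fs
  if (fs <= 200) stop("sampling rate must exceed 200 Hz")
  x <- series$values - mean(series$values)
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, x)
  if (!is.null(notch)) {
    bs <- signal::butter(order,
                         c(notch - notch_halfwidth, notch + notch_halfwidth) / (fs / 2),
                         type = "stop")
    x <- signal::filtfilt(bs, x)
  }
  lfp(x, fs, t0 = series$t0, units = series$units)
}

## ---- Slepian (DPSS) tapers -------------------------------------------------

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` Slepian sequences of length `n` at time-bandwidth product `nw`,
#' computed from the standard symmetric tridiagonal formulation. For long
#' windows the eigenproblem is solved on a 513-point base grid and the
#' tapers are spline-interpolated to length `n` and renormalized, which is
#' accurate to well beyond spectrogram needs. Tapers have unit energy
#' (`sum(v^2) = 1`) and results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default `(k + 1) / 2`).
#' @param k number of tapers.
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = (k + 1) / 2, k = 9) {
  if (k >= 2 * nw + 1)
    warning("k >= 2*nw tapers have poor energy concentration")
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  base_n <- min(n, 513L)
  w <- nw / base_n
  t0 <- 0:(base_n - 1)
  diag_main <- ((base_n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off <- t0[-1] * (base_n - t0[-1]) / 2
  A <- matrix(0, base_n, base_n)
  A[cbind(1:base_n, 1:base_n)] <- diag_main
  A[cbind(1:(base_n - 1), 2:base_n)] <- off
  A[cbind(2:base_n, 1:(base_n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  if (base_n < n) {
    xb <- seq(0, 1, length.out = base_n)
    xo <- seq(0, 1, length.out = n)
    V <- apply(V, 2, function(v) spline(xb, v, xout = xo)$y)
  }
  ## unit energy and a fixed sign convention (positive mean / initial slope)
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    s <- if (abs(sum(v)) > 1e-8) sign(sum(v)) else sign(v[2] - v[1])
    v * ifelse(s == 0, 1, s)
  })
  .taper_cache[[key]] <- V
  V
}

## multitaper PSD of one window (values already extracted), one-sided per Hz
mt_psd_window <- function(x, tapers, fs) {
  n <- length(x)
  Y <- stats::mvfft(tapers * x)
  P <- rowMeans(Mod(Y)^2) / fs
  nf <- floor(n / 2) + 1
  P <- P[seq_len(nf)]
  if (n %% 2 == 0) P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
  else P[2:nf] <- 2 * P[2:nf]
  P
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper spectral estimate: each window is tapered with
#' `n_tapers` Slepian sequences (time-bandwidth product `(n_tapers + 1) / 2`),
#' the tapered periodograms are averaged, and windows advance by
#' `window - overlap` seconds. Defaults follow the standard protocol of nine
#' tapers on a 5 s window with 1 s overlap (4 s step).
#'
#' @param series an [lfp].
#' @param n_tapers number of Slepian tapers.
#' @param window window length in seconds.
#' @param overlap overlap between consecutive windows in seconds; the step
#'   is `window - overlap`. (Set `overlap = window - step` for other steps.)
#' @param nw time-bandwidth product; default `(n_tapers + 1) / 2`.
#' @return Object of class `"spectrogram"`: `times` (window centers, s),
#'   `freqs` (Hz), `power` (freqs x times matrix, power per Hz), `fs`.
#' @export
multitaper_spectrogram <- function(series, n_tapers = 9, window = 5,
                                   overlap = 1, nw = (n_tapers + 1) / 2) {
  stopifnot(inherits(series, "lfp"))
  fs <- series$fs
  nwin <- round(window * fs)
  if (length(series$values) < nwin)
    stop("series shorter than one window")
  step <- window - overlap
  if (step <= 0) stop("`overlap` must be smaller than `window`")
  nstep <- max(1L, round(step * fs))
  starts <- seq(1L, length(series$values) - nwin + 1L, by = nstep)
  tapers <- dpss_tapers(nwin, nw = nw, k = n_tapers)
  nf <- floor(nwin / 2) + 1
  power <- matrix(NA_real_, nf, length(starts))
  for (i in seq_along(starts)) {
    seg <- series$values[starts[i]:(starts[i] + nwin - 1L)]
    power[, i] <- mt_psd_window(seg - mean(seg), tapers, fs)
  }
  structure(list(times = series$t0 + (starts - 1 + nwin / 2) / fs,
                 freqs = seq(0, by = fs / nwin, length.out = nf),
                 power = power, fs = fs,
                 n_tapers = n_tapers, window = window, step = step),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d freqs (0-%.1f Hz), %d tapers, %g s window / %g s step\n",
              length(x$times), length(x$freqs), max(x$freqs),
              x$n_tapers, x$window, x$step))
  invisible(x)
}

#' Multitaper power spectral density
#'
#' Average of the multitaper spectrogram windows of a series; a convenience
#' wrapper used for whole-epoch and per-state spectra.
#'
#' @inheritParams multitaper_spectrogram
#' @return Object of class `"psd"`: `freqs`, `power`, `n_windows`, `empty`.
#' @export
multitaper_psd <- function(series, n_tapers = 9, window = 5, overlap = 1,
                           nw = (n_tapers + 1) / 2) {
  sg <- multitaper_spectrogram(series, n_tapers, window, overlap, nw)
  structure(list(freqs = sg$freqs, power = rowMeans(sg$power),
                 n_windows = length(sg$times), empty = FALSE),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  if (x$empty) cat("<psd> empty (no usable segments)\n")
  else cat(sprintf("<psd> %d freqs (0-%.1f Hz), %d windows averaged\n",
                   length(x$freqs), max(x$freqs), x$n_windows))
  invisible(x)
}

#' Power spectra split by behavioral state
#'
#' Computes separate multitaper PSDs over freezing and non-freezing portions
#' of a recording. The per-sample mask is cut into contiguous same-state
#' segments; segments shorter than one analysis window are skipped (and
#' counted), and windows never straddle a state boundary.
#'
#' @param series an [lfp].
#' @param freezing_mask logical vector, one flag per sample of `series`
#'   (`TRUE` = freezing).
#' @inheritParams multitaper_spectrogram
#' @return List of class `"state_psd"` with elements `freezing` and
#'   `moving` (each a `"psd"`, possibly flagged empty) plus
#'   `n_skipped_segments`.
#' @export
psd_by_state <- function(series, freezing_mask, n_tapers = 9, window = 5,
                         overlap = 1, nw = (n_tapers + 1) / 2) {
  stopifnot(inherits(series, "lfp"))
  if (length(freezing_mask) != length(series$values))
    stop("`freezing_mask` must be aligned with the series (one flag per sample)")
  fs <- series$fs
  nwin <- round(window * fs)
  r <- rle(as.logical(freezing_mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  acc <- list("TRUE" = NULL, "FALSE" = NULL)
  nwinds <- c("TRUE" = 0L, "FALSE" = 0L)
  skipped <- 0L
  for (i in seq_along(r$values)) {
    if (r$lengths[i] < nwin) { skipped <- skipped + 1L; next }
    seg <- lfp(series$values[starts[i]:ends[i]], fs)
    sg <- multitaper_spectrogram(seg, n_tapers, window, overlap, nw)
    key <- as.character(r$values[i])
    tot <- sg$power %*% rep(1, ncol(sg$power))
    acc[[key]] <- if (is.null(acc[[key]])) tot else acc[[key]] + tot
    nwinds[key] <- nwinds[key] + ncol(sg$power)
  }
  freqs <- seq(0, by = fs / nwin, length.out = floor(nwin / 2) + 1)
  mk <- function(key) {
    if (nwinds[key] == 0L)
      structure(list(freqs = freqs, power = rep(NA_real_, length(freqs)),
                     n_windows = 0L, empty = TRUE), class = "psd")
    else
      structure(list(freqs = freqs, power = as.numeric(acc[[key]]) / nwinds[key],
                     n_windows = nwinds[[key]], empty = FALSE), class = "psd")
  }
  structure(list(freezing = mk("TRUE"), moving = mk("FALSE"),
                 n_skipped_segments = skipped),
            class = "state_psd")
}

#' Integrated band power of a PSD
#'
#' @param psd a `"psd"` object.
#' @param band (low, high) in Hz; default the 4-10 Hz theta band.
#' @return Power integrated over the band (trapezoidal rule).
#' @export
band_power <- function(psd, band = c(4, 10)) {
  stopifnot(inherits(psd, "psd"))
  i <- psd$freqs >= band[1] & psd$freqs <= band[2]
  f <- psd$freqs[i]
  p <- psd$power[i]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Peak frequency of a PSD within a band
#'
#' @inheritParams band_power
#' @return Frequency (Hz) of maximal power inside the band.
#' @export
peak_frequency <- function(psd, band = c(4, 10)) {
  stopifnot(inherits(psd, "psd"))
  i <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  psd$freqs[i[which.max(psd$power[i])]]
}
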