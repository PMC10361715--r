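#' Band-limited amplitude envelope
#'
#' Magnitude of the analytic signal of a zero-phase fourth-order Butterworth
#' bandpassed series: the instantaneous amplitude in the requested band,
#' e.g. slow gamma (35-55 Hz) or mid gamma (55-85 Hz).
#'
#' @param series an [lfp].
#' @param band (low, high) in Hz inside (0, fs/2).
#' @param order Butterworth order (default 4).
#' @return An [lfp] of instantaneous amplitude.
#' @export
band_envelope <- function(series, band, order = 4) {
  stopifnot(inherits(series, "lfp"))
  fs <- series$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2])
    stop("`band` must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, series$values)
  lfp(Mod(analytic_signal(y)), fs, t0 = series$t0, units = series$units)
}

#' Phase-amplitude modulation index
#'
#' The Kullback-Leibler modulation index of phase-amplitude coupling: the
#' amplitude samples are averaged in `n_bins` equal phase bins (twenty
#' 18-degree bins by default), the per-bin means are normalized to a
#' distribution P, and
#' `MI = D_KL(P, U) / log(n_bins)`
#' where U is the uniform distribution — 0 for no coupling, 1 when all
#' amplitude concentrates in a single bin. Empty bins contribute 0
#' (0 log 0 := 0) and are flagged.
#'
#' @param phase an [lfp] of wrapped phase, or a numeric vector of phases in
#'   (-pi, pi].
#' @param amplitude an [lfp] of instantaneous amplitude, or a numeric
#'   vector; must be time-aligned and of equal length with `phase`.
#' @param n_bins number of phase bins (default 20). Bins partition the
#'   circle as half-open intervals `[left, right)` with the last bin closed.
#' @param phase_band,amp_band optional (low, high) Hz labels recorded in the
#'   result.
#' @return Object of class `"pac_result"`: `n_bins`, `bin_centers`,
#'   `mean_amp` (normalized, sums to 1), `mi`, `n_empty_bins`,
#'   `phase_band`, `amp_band`. With an all-zero amplitude the MI is `NA`
#'   (undefined) with a warning.
#' @examples
#' ph <- runif(5000, -pi, pi)
#' modulation_index(ph, 1 + 0.8 * cos(ph))$mi
#' @export
modulation_index <- function(phase, amplitude, n_bins = 20,
                             phase_band = NULL, amp_band = NULL) {
  p <- if (inherits(phase, "lfp")) phase$values else as.numeric(phase)
  a <- if (inherits(amplitude, "lfp")) amplitude$values else as.numeric(amplitude)
  if (length(p) != length(a))
    stop("`phase` and `amplitude` must have equal length")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (any(a < 0)) stop("`amplitude` must be non-negative")
  idx <- pmin(pmax(ceiling((p + pi) / (2 * pi) * n_bins), 1L), n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  sums <- rowsum(a, idx)                 # sorted by bin index
  occupied <- as.integer(rownames(sums))
  m <- numeric(n_bins)
  m[occupied] <- sums[, 1] / cnt[occupied]
  n_empty <- sum(cnt == 0)
  width <- 2 * pi / n_bins
  centers <- -pi + width * (seq_len(n_bins) - 0.5)
  if (sum(m) <= 0) {
    warning("all-zero amplitude: modulation index undefined")
    pdist <- rep(NA_real_, n_bins)
    mi <- NA_real_
  } else {
    pdist <- m / sum(m)
    nz <- pdist > 0
    mi <- sum(pdist[nz] * log(pdist[nz] * n_bins)) / log(n_bins)
  }
  if (n_empty > 0 && !is.na(mi))
    warning(sprintf("%d empty phase bin(s); MI computed over occupied bins",
                    n_empty))
  structure(list(n_bins = n_bins, bin_centers = centers, mean_amp = pdist,
                 mi = mi, n_empty_bins = n_empty,
                 phase_band = phase_band, amp_band = amp_band),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> MI = %.4g over %d phase bins", x$mi, x$n_bins))
  if (!is.null(x$phase_band))
    cat(sprintf(" | phase %g-%g Hz", x$phase_band[1], x$phase_band[2]))
  if (!is.null(x$amp_band))
    cat(sprintf(" | amp %g-%g Hz", x$amp_band[1], x$amp_band[2]))
  cat("\n")
  invisible(x)
}

#' Theta-gamma modulation index of a raw LFP
#'
#' Convenience wrapper: extracts the phase of `phase_band` (Hilbert phase of
#' the Butterworth-filtered signal) and the envelope of `amp_band`, then
#' computes the KL modulation index.
#'
#' @param series an [lfp].
#' @param phase_band phase (theta) band in Hz, default 4-10.
#' @param amp_band amplitude (gamma) band in Hz, default mid gamma 55-85.
#' @param n_bins number of phase bins.
#' @param mask optional logical per-sample mask restricting which samples
#'   enter the MI (e.g. a behavioral-state or epoch mask).
#' @return A `"pac_result"`.
#' @export
pac_mi <- function(series, phase_band = c(4, 10), amp_band = c(55, 85),
                   n_bins = 20, mask = NULL) {
  ph <- instantaneous_phase(series, phase_band)
  am <- band_envelope(series, amp_band)
  p <- ph$values
  a <- am$values
  if (!is.null(mask)) {
    if (length(mask) != length(p))
      stop("`mask` must be aligned with the series")
    p <- p[mask]
    a <- a[mask]
  }
  modulation_index(p, a, n_bins, phase_band = phase_band, amp_band = amp_band)
}

#' Theta-gamma comodulogram
#'
#' The modulation index evaluated over a grid of (phase band, amplitude
#' band) pairs. Following the standard layout, phase frequencies are scanned
#' in 4 Hz-wide bands at 1 Hz steps and amplitude frequencies in 20 Hz-wide
#' bands at 5 Hz steps. Cells whose bands would exceed the Nyquist frequency
#' (or whose computation fails) are marked `NA`, not zero.
#'
#' @param series an [lfp], at least 10 cycles of the slowest phase band.
#' @param phase_centers,amp_centers numeric vectors of band center
#'   frequencies in Hz.
#' @param phase_bw,amp_bw band widths in Hz.
#' @param n_bins phase bins per MI evaluation.
#' @return Object of class `"comodulogram"`: `phase_band_centers`,
#'   `amp_band_centers`, `mi_matrix` (phase x amplitude), `phase_bw`,
#'   `amp_bw`.
#' @export
comodulogram <- function(series, phase_centers = 4:10,
                         amp_centers = seq(30, 90, by = 5),
                         phase_bw = 4, amp_bw = 20, n_bins = 20) {
  stopifnot(inherits(series, "lfp"))
  slowest <- min(phase_centers) - phase_bw / 2
  if (lfp_duration(series) < 10 / max(slowest, 0.5))
    stop("series shorter than 10 cycles of the slowest phase band")
  fs <- series$fs
  phases <- lapply(phase_centers, function(cf) {
    band <- cf + c(-0.5, 0.5) * phase_bw
    if (band[1] <= 0 || band[2] >= fs / 2) return(NULL)
    instantaneous_phase(series, band)$values
  })
  amps <- lapply(amp_centers, function(cf) {
    band <- cf + c(-0.5, 0.5) * amp_bw
    if (band[1] <= 0 || band[2] >= fs / 2) return(NULL)
    band_envelope(series, band)$values
  })
  mi <- matrix(NA_real_, length(phase_centers), length(amp_centers),
               dimnames = list(phase = phase_centers, amp = amp_centers))
  for (i in seq_along(phase_centers)) {
    if (is.null(phases[[i]])) next
    for (j in seq_along(amp_centers)) {
      if (is.null(amps[[j]])) next
      mi[i, j] <- tryCatch(
        suppressWarnings(modulation_index(phases[[i]], amps[[j]], n_bins)$mi),
        error = function(e) NA_real_)
    }
  }
  structure(list(phase_band_centers = phase_centers,
                 amp_band_centers = amp_centers,
                 mi_matrix = mi, phase_bw = phase_bw, amp_bw = amp_bw,
                 n_bins = n_bins),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  am <- comodulogram_argmax(x)
  cat(sprintf("<comodulogram> %d x %d cells; max MI %.4g at phase %g Hz / amp %g Hz\n",
              length(x$phase_band_centers), length(x$amp_band_centers),
              am$mi, am$phase_center, am$amp_center))
  invisible(x)
}

#' Location of the comodulogram maximum
#'
#' @param x a `"comodulogram"`.
#' @return List with `phase_center`, `amp_center`, `phase_band`, `amp_band`
#'   and `mi` of the maximal cell.
#' @export
comodulogram_argmax <- function(x) {
  stopifnot(inherits(x, "comodulogram"))
  if (all(is.na(x$mi_matrix))) stop("comodulogram has no finite cells")
  ij <- which(x$mi_matrix == max(x$mi_matrix, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pc <- x$phase_band_centers[ij[1]]
  ac <- x$amp_band_centers[ij[2]]
  list(phase_center = pc, amp_center = ac,
       phase_band = pc + c(-0.5, 0.5) * x$phase_bw,
       amp_band = ac + c(-0.5, 0.5) * x$amp_bw,
       mi = x$mi_matrix[ij[1], ij[2]])
}

#' Preferred coupling phase
#'
#' Circular mean of the phase-bin centers weighted by the normalized
#' amplitude distribution: the theta phase at which the fast-rhythm
#' amplitude concentrates.
#'
#' @param result a `"pac_result"`.
#' @return Phase in (-pi, pi], or `NA` with a warning when the distribution
#'   has no preferred direction (uniform or antipodally balanced).
#' @export
preferred_phase <- function(result) {
  stopifnot(inherits(result, "pac_result"))
  out <- circular_mean(result$bin_centers, result$mean_amp)
  if (is.na(out)) warning("amplitude distribution has no preferred direction")
  out
}
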