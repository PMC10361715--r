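#' Post-hoc instantaneous theta phase
#'
#' Zero-phase (forward-backward) fourth-order Butterworth bandpass followed
#' by the Hilbert analytic-signal phase. Convention: a local maximum of the
#' bandpassed signal maps to phase 0 (theta peak) and a minimum to +/- pi
#' (trough); phases are wrapped to (-pi, pi].
#'
#' This is the offline evaluation path, deliberately distinct from the
#' causal FIR of the real-time module.
#'
#' @param series an [lfp].
#' @param band bandpass (low, high) in Hz, default the 4-10 Hz theta band.
#' @param order Butterworth order (default 4).
#' @return An [lfp] of wrapped phase (radians).
#' @export
instantaneous_phase <- function(series, band = c(4, 10), order = 4) {
  stopifnot(inherits(series, "lfp"))
  fs <- series$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2])
    stop("`band` must satisfy 0 < low < high < fs/2")
  if (lfp_duration(series) < 3 / band[1])
    stop("series shorter than three cycles of the lower band edge; ",
         "filter transients would dominate")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, series$values)
  lfp(wrap_phase(Arg(analytic_signal(y))), fs, t0 = series$t0, units = "rad")
}

## unwrapped phase interpolated at arbitrary times (NA outside the series)
phase_at <- function(phase, times) {
  psi <- unwrap_phase(phase$values)
  approx(lfp_times(phase), psi, xout = times, rule = 1)$y
}

#' Theta extrema implied by a phase series
#'
#' Peak times are the upward crossings of the unwrapped phase through
#' multiples of 2*pi, trough times the crossings through pi + 2*pi*k
#' (linearly interpolated between samples).
#'
#' @param phase an [lfp] of wrapped phase, e.g. from [instantaneous_phase()].
#' @return List with `peak_times` and `trough_times` (seconds).
#' @export
phase_extrema <- function(phase) {
  stopifnot(inherits(phase, "lfp"))
  psi <- unwrap_phase(phase$values)
  tt <- lfp_times(phase)
  crossings <- function(targets) {
    out <- numeric(0)
    for (g in targets) {
      i <- which(psi[-length(psi)] < g & psi[-1] >= g)
      out <- c(out, tt[i] + (g - psi[i]) / (psi[i + 1] - psi[i]) / phase$fs * 1)
    }
    sort(out)
  }
  k <- seq(floor(min(psi) / (2 * pi)) - 1, ceiling(max(psi) / (2 * pi)) + 1)
  list(peak_times = crossings(2 * pi * k),
       trough_times = crossings(pi + 2 * pi * k))
}

## normalize the many accepted extrema representations to peak/trough lists
extrema_times <- function(extrema) {
  if (inherits(extrema, "theta_truth"))
    return(list(peak_times = extrema$peak_times,
                trough_times = extrema$trough_times))
  if (inherits(extrema, "cycle_track"))
    return(list(
      peak_times = extrema$extremum_times[extrema$extremum_kinds == "peak"],
      trough_times = extrema$extremum_times[extrema$extremum_kinds == "trough"]))
  if (is.list(extrema) && all(c("peak_times", "trough_times") %in% names(extrema)))
    return(extrema[c("peak_times", "trough_times")])
  stop("`extrema` must be a theta_truth, a cycle_track, or a list with ",
       "peak_times and trough_times")
}

#' Classify stimulation events as on- or off-target
#'
#' An event is on target when its theta phase lies within `tolerance`
#' (default a quarter cycle, pi/4) of the target phase: 0 for the peak,
#' +/- pi for the trough. A phase error of exactly `tolerance` counts as
#' on-target.
#'
#' @param events an [event_train].
#' @param phase an [lfp] of wrapped phase.
#' @param target `"peak"` or `"trough"`.
#' @param tolerance phase tolerance in radians (default pi/4).
#' @return Data frame with columns `time`, `phase`, `on_target`; events
#'   outside the phase series' time range are dropped, with the count in
#'   attribute `n_skipped` (and a warning).
#' @export
classify_stimulations <- function(events, phase, target = c("peak", "trough"),
                                  tolerance = pi / 4) {
  stopifnot(inherits(events, "event_train"), inherits(phase, "lfp"))
  target <- match.arg(target)
  ph <- wrap_phase(phase_at(phase, events$times))
  keep <- !is.na(ph)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning(sprintf("%d event(s) outside the phase series were skipped",
                    n_skipped))
  target_phase <- if (target == "peak") 0 else pi
  err <- abs(wrap_phase(ph[keep] - target_phase))
  out <- data.frame(time = events$times[keep], phase = ph[keep],
                    on_target = err <= tolerance + 1e-12)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Phase-targeting confusion matrix (sensitivity and specificity)
#'
#' Scores a stimulation train against theta extrema. Each extremum owns a
#' quarter-cycle phase window (+/- `tolerance` about its own phase); an
#' in-phase extremum (same kind as the target) counts as a true positive
#' when at least one event falls inside its window, and an out-of-phase
#' extremum (the opposite kind) counts as a true negative when no event
#' does. TPR = hit in-phase extrema / all in-phase extrema;
#' TNR = unstimulated out-of-phase extrema / all out-of-phase extrema.
#'
#' Windows are phase windows, not time windows, so the criterion is
#' frequency-invariant; event/extremum pairing uses the unwrapped phase, so
#' each window belongs to a single theta cycle.
#'
#' @param events an [event_train].
#' @param extrema a `"theta_truth"`, a `"cycle_track"`, or a list with
#'   `peak_times` and `trough_times`.
#' @param phase an [lfp] of wrapped phase on the same time base.
#' @param target `"peak"` or `"trough"`.
#' @param tolerance phase half-window in radians (default pi/4, the
#'   quarter-cycle criterion).
#' @param swap_phase_labels set `TRUE` when the electrode was post hoc found
#'   below the CA1 pyramidal layer hilus reversal (e.g. in DG), where theta
#'   is inverted: the phase is rotated by pi and peak/trough extrema are
#'   exchanged, which exactly swaps peak-target and trough-target results.
#' @return An object of class `"phase_eval"` with the per-event phases,
#'   confusion counts, `tpr` and `tnr`. If a kind has zero extrema the
#'   corresponding rate is `NA` with a warning (never silently 0).
#' @export
phase_confusion_matrix <- function(events, extrema, phase,
                                   target = c("peak", "trough"),
                                   tolerance = pi / 4,
                                   swap_phase_labels = FALSE) {
  stopifnot(inherits(events, "event_train"), inherits(phase, "lfp"))
  target <- match.arg(target)
  ex <- extrema_times(extrema)
  if (swap_phase_labels) {
    phase <- lfp(wrap_phase(phase$values + pi), phase$fs, t0 = phase$t0,
                 units = "rad")
    ex <- list(peak_times = ex$trough_times, trough_times = ex$peak_times)
  }
  psi <- unwrap_phase(phase$values)
  tt <- lfp_times(phase)
  at <- function(x) approx(tt, psi, xout = x, rule = 1)$y
  pe <- at(events$times)
  n_skipped <- sum(is.na(pe))
  if (n_skipped > 0)
    warning(sprintf("%d event(s) outside the phase series were skipped",
                    n_skipped))
  pe <- pe[!is.na(pe)]
  in_times <- if (target == "peak") ex$peak_times else ex$trough_times
  out_times <- if (target == "peak") ex$trough_times else ex$peak_times
  hit <- function(x) {
    px <- at(x)
    vapply(px, function(p) !is.na(p) && length(pe) > 0 &&
             any(abs(pe - p) <= tolerance + 1e-12), logical(1))
  }
  in_hit <- hit(in_times)
  out_hit <- hit(out_times)
  tol_eps <- tolerance + 1e-12
  target_phase <- if (target == "peak") 0 else pi
  stim_phases <- wrap_phase(pe)
  res <- structure(list(
    stim_phases = stim_phases,
    target = target, tolerance = tolerance,
    n_inphase_extrema = length(in_times),
    n_outphase_extrema = length(out_times),
    n_inphase_stimulated = sum(in_hit),
    n_outphase_stimulated = sum(out_hit),
    n_stim_on_target = sum(abs(wrap_phase(stim_phases - target_phase)) <= tol_eps),
    tpr = NA_real_, tnr = NA_real_,
    n_skipped_events = n_skipped), class = "phase_eval")
  if (length(in_times) == 0L)
    warning("no in-phase extrema: TPR undefined")
  else res$tpr <- mean(in_hit)
  if (length(out_times) == 0L)
    warning("no out-of-phase extrema: TNR undefined")
  else res$tnr <- mean(!out_hit)
  res
}

#' @export
print.phase_eval <- function(x, ...) {
  cat(sprintf("<phase_eval> target %s (+/- %.3f rad): TPR %.1f%% (%d/%d), TNR %.1f%% (%d/%d), %d events\n",
              x$target, x$tolerance, 100 * x$tpr, x$n_inphase_stimulated,
              x$n_inphase_extrema, 100 * x$tnr,
              x$n_outphase_extrema - x$n_outphase_stimulated,
              x$n_outphase_extrema, length(x$stim_phases)))
  invisible(x)
}

#' Normalized circular histogram of stimulation phases
#'
#' @param events an [event_train].
#' @param phase an [lfp] of wrapped phase.
#' @param n_bins number of equal bins covering (-pi, pi] (>= 4).
#' @return A list of class `"phase_histogram"`: `breaks`, `mids`,
#'   `fraction` (sums to 1), `n_events`; with no events all fractions are 0
#'   and the `empty` flag is set.
#' @export
phase_histogram <- function(events, phase, n_bins = 20) {
  stopifnot(inherits(events, "event_train"), inherits(phase, "lfp"))
  if (n_bins < 4) stop("`n_bins` must be >= 4")
  ph <- wrap_phase(phase_at(phase, events$times))
  ph <- ph[!is.na(ph)]
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(pmax(ceiling((ph + pi) / (2 * pi) * n_bins), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  empty <- length(ph) == 0L
  fraction <- if (empty) numeric(n_bins) else counts / length(ph)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 fraction = fraction, counts = counts,
                 n_events = length(ph), empty = empty),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d bins, %d events%s\n", length(x$mids),
              x$n_events, if (x$empty) " (empty)" else ""))
  invisible(x)
}
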