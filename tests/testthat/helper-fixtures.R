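# Shared fixture builders: everything is generated in code at test time.

# A pure cosine lfp (peak at t = 0).
cosine_lfp <- function(freq = 6, duration = 2, fs = 1000, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  lfp(amp * cos(2 * pi * freq * t), fs)
}

# Short synthetic theta session under the standard study conditions.
quick_session <- function(duration = 10, seed = 1, ...) {
  generate_theta_lfp(synth_params(duration = duration, seed = seed, ...))
}

# Brute-force per-extremum enumeration: the independent oracle for the
# quarter-cycle confusion matrix. For every extremum it loops over all
# events and checks, with wrapped phase differences plus a same-cycle
# constraint (the unwrapped phase gap must stay below half a cycle's 2*pi),
# whether any event sits in the extremum's quarter-cycle phase window.
brute_confusion <- function(event_times, extrema, phase, target,
                            tol = pi / 4) {
  tt <- lfp_times(phase)
  ph <- phase$values
  ex <- if (inherits(extrema, "theta_truth"))
    list(peak_times = extrema$peak_times, trough_times = extrema$trough_times)
  else extrema
  psi <- unwrap_phase(ph)
  pe <- approx(tt, psi, xout = event_times)$y
  pe <- pe[!is.na(pe)]
  scan_one <- function(tx) {
    px <- approx(tt, psi, xout = tx)$y
    hit <- FALSE
    for (e in pe)
      if (abs(wrap_phase(e - px)) <= tol + 1e-12 && abs(e - px) <= pi)
        hit <- TRUE
    hit
  }
  in_t <- if (target == "peak") ex$peak_times else ex$trough_times
  out_t <- if (target == "peak") ex$trough_times else ex$peak_times
  in_hit <- vapply(in_t, scan_one, logical(1))
  out_hit <- vapply(out_t, scan_one, logical(1))
  list(tpr = mean(in_hit), tnr = mean(!out_hit),
       n_in = length(in_t), n_out = length(out_t),
       n_in_hit = sum(in_hit), n_out_hit = sum(out_hit))
}

# Frequency response of an FIR filter at frequency f (Hz) — direct
# evaluation of the transfer polynomial, independent of signal::filter.
fir_response <- function(taps, f, fs) {
  abs(sum(taps * exp(-1i * 2 * pi * f / fs * (seq_along(taps) - 1))))
}
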