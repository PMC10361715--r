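#' Closed-loop stimulation configuration
#'
#' Settings of the streaming phase-prediction stimulator and of the
#' fixed-frequency controls. The causal pipeline is: FIR bandpass in the
#' theta range, streaming extremum detection, prediction of the next target
#' extremum by averaging recent cycle durations, and a TTL event at the
#' predicted time (gated by the epoch design and a refractory period).
#'
#' @param mode `"peak"` or `"trough"` for phase-specific stimulation,
#'   `"fixed"` for open-loop fixed-frequency stimulation.
#' @param fixed_rate rate in Hz for `mode = "fixed"` (6 and 20 Hz are the
#'   usual controls).
#' @param fir_band theta passband (low, high) in Hz of the causal FIR filter.
#' @param fir_order FIR order (taps - 1). Even orders give an exact group
#'   delay of `fir_order / 2` samples. The default (200 taps at 1 kHz, i.e.
#'   100 ms delay) keeps the detection-to-stimulation horizon within one
#'   theta cycle.
#' @param n_cycles_avg number of most recent cycle durations averaged when
#'   predicting the next extremum.
#' @param refractory minimum spacing between TTL events in seconds; the
#'   default, 50 ms, is half the shortest theta period (10 Hz) and prevents
#'   double stimulation within one cycle.
#' @param pulse_width laser pulse width in seconds; stored for provenance
#'   only (events are treated as instants).
#' @param epoch_design an [epoch_design]; TTLs are emitted only inside Stim
#'   epochs.
#' @return A list of class `"stim_config"`.
#' @export
stim_config <- function(mode = c("peak", "trough", "fixed"),
                        fixed_rate = 6,
                        fir_band = c(4, 10), fir_order = 200,
                        n_cycles_avg = 3, refractory = 0.05,
                        pulse_width = 0.015,
                        epoch_design = thetastim::epoch_design()) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.numeric(fixed_rate) || fixed_rate <= 0))
    stop("`fixed_rate` must be > 0 when mode = \"fixed\"")
  if (refractory < 0) stop("`refractory` must be >= 0")
  if (n_cycles_avg < 1) stop("`n_cycles_avg` must be >= 1")
  if (length(fir_band) != 2L || fir_band[1] <= 0 || fir_band[1] >= fir_band[2])
    stop("`fir_band` must be an increasing (low, high) pair of positive Hz")
  if (fir_order < 2) stop("`fir_order` must be >= 2")
  structure(list(mode = mode, fixed_rate = fixed_rate,
                 fir_band = as.numeric(fir_band),
                 fir_order = as.integer(fir_order),
                 n_cycles_avg = as.integer(n_cycles_avg),
                 refractory = refractory, pulse_width = pulse_width,
                 epoch_design = epoch_design),
            class = "stim_config")
}

#' @export
print.stim_config <- function(x, ...) {
  cat(sprintf("<stim_config> mode %s | FIR %g-%g Hz order %d | avg %d cycles | refractory %g s\n",
              x$mode, x$fir_band[1], x$fir_band[2], x$fir_order,
              x$n_cycles_avg, x$refractory))
  invisible(x)
}

#' Causal FIR bandpass filter
#'
#' Streaming (causal) linear-phase FIR bandpass, the first stage of the
#' real-time pipeline: the output at time t uses only samples at or before t.
#' The symmetric FIR introduces a known constant group delay of
#' `order / 2` samples, reported as attributes `group_delay` (seconds) and
#' `group_delay_samples` so later stages can compensate.
#'
#' @param series an [lfp].
#' @param band passband (low, high) in Hz; must lie inside (0, fs/2).
#' @param order FIR order (number of taps minus one); even.
#' @return Filtered [lfp], sample-aligned with the input, with group-delay
#'   attributes.
#' @export
stream_filter <- function(series, band = c(4, 10), order = 200) {
  stopifnot(inherits(series, "lfp"))
  fs <- series$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2])
    stop("`band` must satisfy 0 < low < high < fs/2")
  if (order %% 2 == 1) order <- order + 1
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(b, series$values))
  out <- lfp(y, fs, t0 = series$t0, units = series$units)
  attr(out, "group_delay_samples") <- order / 2
  attr(out, "group_delay") <- order / 2 / fs
  attr(out, "taps") <- as.numeric(b)
  out
}

#' Streaming detection of theta cycle extrema
#'
#' Causal extremum confirmation on a filtered series: a turning point is
#' confirmed once the sign change of the first difference has been sustained
#' for at least 3 samples, so an extremum at sample i is only known at sample
#' i + 3. Alternation is enforced (a same-kind candidate replaces the
#' previous extremum if more extreme; an opposite-kind candidate is accepted
#' only after a minimum gap of a quarter of the shortest passband period).
#'
#' @param filtered an [lfp], typically the output of [stream_filter()].
#' @param config a [stim_config]; its `fir_band` fixes the minimum
#'   peak-to-trough gap.
#' @return An object of class `"cycle_track"`: `extremum_times`,
#'   `extremum_kinds` (`"peak"`/`"trough"`), `extremum_values`,
#'   `confirm_times` (when each extremum became observable). Empty on flat
#'   input.
#' @export
detect_cycles <- function(filtered, config = stim_config()) {
  stopifnot(inherits(filtered, "lfp"), inherits(config, "stim_config"))
  x <- filtered$values
  fs <- filtered$fs
  n <- length(x)
  empty <- structure(list(extremum_times = numeric(0),
                          extremum_kinds = character(0),
                          extremum_values = numeric(0),
                          confirm_times = numeric(0)),
                     class = "cycle_track")
  if (n < 6L) return(empty)
  d <- diff(x)
  k <- seq_len(n - 4L)
  pk <- which(d[k] > 0 & d[k + 1] < 0 & d[k + 2] < 0 & d[k + 3] < 0)
  tr <- which(d[k] < 0 & d[k + 1] > 0 & d[k + 2] > 0 & d[k + 3] > 0)
  if (!length(pk) && !length(tr)) return(empty)
  cand_idx <- c(pk, tr) + 1L                 # sample index of the extremum
  cand_kind <- rep(c("peak", "trough"), c(length(pk), length(tr)))
  o <- order(cand_idx)
  cand_idx <- cand_idx[o]
  cand_kind <- cand_kind[o]
  min_gap <- 0.25 / config$fir_band[2]
  times <- kinds <- vals <- confs <- list()
  m <- 0L
  for (j in seq_along(cand_idx)) {
    ti <- filtered$t0 + (cand_idx[j] - 1) / fs
    vi <- x[cand_idx[j]]
    ci <- filtered$t0 + (cand_idx[j] + 2) / fs   # confirmed 3 samples later
    if (m == 0L) {
      m <- 1L
      times[[m]] <- ti; kinds[[m]] <- cand_kind[j]
      vals[[m]] <- vi; confs[[m]] <- ci
    } else if (cand_kind[j] == kinds[[m]]) {
      better <- if (cand_kind[j] == "peak") vi > vals[[m]] else vi < vals[[m]]
      if (better) {
        times[[m]] <- ti; vals[[m]] <- vi; confs[[m]] <- ci
      }
    } else if (ti - times[[m]] >= min_gap) {
      m <- m + 1L
      times[[m]] <- ti; kinds[[m]] <- cand_kind[j]
      vals[[m]] <- vi; confs[[m]] <- ci
    }
  }
  structure(list(extremum_times = unlist(times),
                 extremum_kinds = unlist(kinds),
                 extremum_values = unlist(vals),
                 confirm_times = unlist(confs)),
            class = "cycle_track")
}

#' @export
print.cycle_track <- function(x, ...) {
  cat(sprintf("<cycle_track> %d extrema (%d peaks, %d troughs)\n",
              length(x$extremum_times),
              sum(x$extremum_kinds == "peak"),
              sum(x$extremum_kinds == "trough")))
  invisible(x)
}

#' Cycle durations of a track
#'
#' Durations between consecutive same-kind extrema.
#'
#' @param track a `"cycle_track"`.
#' @param kind `"peak"` or `"trough"`.
#' @return Numeric vector of durations in seconds.
#' @export
cycle_durations <- function(track, kind = c("peak", "trough")) {
  kind <- match.arg(kind)
  diff(track$extremum_times[track$extremum_kinds == kind])
}

#' Predict the time of the next target extremum
#'
#' The closed-loop prediction rule: the next extremum of the target kind is
#' expected one mean cycle after the last one, where the mean is taken over
#' the most recent `n_cycles_avg` same-kind cycle durations. If the predicted
#' time has already passed (`<= now`), it is advanced by whole mean cycles
#' until it lies in the future.
#'
#' @param track a `"cycle_track"` of confirmed extrema.
#' @param target `"peak"` or `"trough"`.
#' @param now current time in seconds; the prediction is forced beyond it.
#' @param config a [stim_config] (supplies `n_cycles_avg`).
#' @return Predicted time in seconds, or `NA_real_` when no prediction can
#'   be made yet (fewer than two target-kind extrema observed).
#' @export
predict_next_extremum <- function(track, target = c("peak", "trough"),
                                  now, config = stim_config()) {
  target <- match.arg(target)
  tt <- track$extremum_times[track$extremum_kinds == target]
  if (length(tt) < 2L) return(NA_real_)
  durs <- diff(tt)
  m <- mean(tail(durs, config$n_cycles_avg))
  pred <- tt[length(tt)] + m
  while (pred <= now) pred <- pred + m
  pred
}

#' Run the closed-loop phase-specific stimulator
#'
#' Full causal emulation of the real-time algorithm: the LFP is bandpass
#' filtered with a causal FIR, extrema are confirmed from the stream, and at
#' each confirmed target-kind extremum the next one is predicted by
#' averaging recent cycle durations. The prediction is translated from
#' filtered-signal time back to input time by subtracting the FIR's constant
#' group delay, advanced by whole mean cycles if necessary so it stays in
#' the future, and a TTL event is emitted at that time provided it falls in
#' a Stim epoch and respects the refractory period. A newer prediction
#' supersedes a pending one that has not yet fired.
#'
#' @param series raw [lfp].
#' @param config a [stim_config] with `mode` `"peak"` or `"trough"`.
#' @return An [event_train] of TTL times (seconds), with the configuration
#'   attached.
#' @export
run_closed_loop <- function(series, config = stim_config()) {
  stopifnot(inherits(series, "lfp"), inherits(config, "stim_config"))
  if (config$mode == "fixed")
    stop("mode \"fixed\" is handled by run_fixed_frequency(), not the closed loop")
  target <- config$mode
  filt <- stream_filter(series, config$fir_band, config$fir_order)
  delay <- attr(filt, "group_delay")
  track <- detect_cycles(filt, config)
  sel <- track$extremum_kinds == target
  tk <- track$extremum_times[sel]
  ck <- track$confirm_times[sel]
  dur_total <- lfp_duration(series)
  events <- numeric(0)
  pending <- NA_real_
  commit <- function(t_ev) {
    if (t_ev < dur_total && in_stim_epoch(t_ev, config$epoch_design) &&
        (length(events) == 0L || t_ev - events[length(events)] >= config$refractory))
      events[length(events) + 1L] <<- t_ev
  }
  for (j in seq_along(tk)) {
    if (j < 2L) next
    now <- ck[j]
    if (!is.na(pending) && pending <= now) {
      commit(pending)
      pending <- NA_real_
    }
    m <- mean(tail(diff(tk[seq_len(j)]), config$n_cycles_avg))
    t_ev <- tk[j] + m - delay
    while (t_ev <= now) t_ev <- t_ev + m
    pending <- t_ev
  }
  if (!is.na(pending)) commit(pending)
  event_train(events, mode = target,
              config = config[c("fir_band", "fir_order", "n_cycles_avg",
                                "refractory", "pulse_width")])
}

#' Fixed-frequency stimulation schedule
#'
#' Open-loop control: TTL events at exact `1/rate` spacing within each Stim
#' epoch, starting at the epoch onset.
#'
#' @param design an [epoch_design].
#' @param rate stimulation rate in Hz (> 0); 6 and 20 Hz are the standard
#'   controls.
#' @return An [event_train] with mode `"fixed"`.
#' @examples
#' length(run_fixed_frequency(epoch_design("Stim", 3), 20))  # 60 events
#' @export
run_fixed_frequency <- function(design, rate) {
  stopifnot(inherits(design, "epoch_design"))
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  iv <- stim_intervals(design)
  times <- numeric(0)
  for (r in seq_len(nrow(iv))) {
    dur <- iv[r, 2] - iv[r, 1]
    k <- ceiling(dur * rate - 1e-9)
    times <- c(times, iv[r, 1] + (seq_len(k) - 1) / rate)
  }
  event_train(times, mode = "fixed", config = list(rate = rate))
}
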