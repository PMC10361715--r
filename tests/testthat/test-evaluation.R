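test_that("instantaneous phase follows the cosine convention", {
  x <- cosine_lfp(6, duration = 4)
  ph <- instantaneous_phase(x)
  tt <- lfp_times(ph)
  core <- tt > 1 & tt < 3                   # away from edge transients
  # maxima at phase 0: phase magnitude small wherever cos is ~1
  at_max <- core & abs(x$values - 1) < 1e-4
  expect_true(all(abs(ph$values[at_max]) < 0.05))
  # minima at +/- pi
  at_min <- core & abs(x$values + 1) < 1e-4
  expect_true(all(abs(abs(ph$values[at_min]) - pi) < 0.05))
  # monotonically increasing modulo wrap
  dpsi <- diff(unwrap_phase(ph$values[core]))
  expect_true(all(dpsi > 0))
  expect_error(instantaneous_phase(lfp(rnorm(100), 1000)), "shorter")
})

test_that("estimated phase agrees with ground truth on noisy theta", {
  p <- synth_params(duration = 30, theta_amp = 1, noise_scale = 1 / sqrt(20),
                    seed = 5)
  s <- generate_theta_lfp(p)
  ph <- instantaneous_phase(s$signal)
  core <- seq(2000, 28000)
  r <- circular_correlation(ph$values[core],
                            s$truth$instantaneous_phase$values[core])
  expect_gt(r, 0.95)
})

test_that("events are classified on/off target by the quarter-cycle rule", {
  # phase ramp covering (-pi, pi] at 1 rad resolution of time
  fs <- 1000
  x <- cosine_lfp(6, duration = 4)
  ph <- instantaneous_phase(x)
  t_of_phase <- function(target) {
    tt <- lfp_times(ph)
    cand <- tt > 1 & tt < 2
    tt[cand][which.min(abs(wrap_phase(ph$values[cand] - target)))]
  }
  ev <- event_train(sort(c(t_of_phase(0.5), t_of_phase(2.9), t_of_phase(pi / 2))))
  pk <- classify_stimulations(ev, ph, "peak")
  tr <- classify_stimulations(ev, ph, "trough")
  get <- function(df, target) df$on_target[which.min(abs(wrap_phase(df$phase - target)))]
  expect_true(get(pk, 0.5))                 # 0.5 < pi/4 from peak? no: 0.5 < 0.785
  expect_false(get(pk, pi / 2))             # pi/2 off target for peak
  expect_true(get(tr, 2.9))                 # |2.9 - pi| ~ 0.24 on target
  # boundary: exactly tolerance counts as on-target
  df <- classify_stimulations(event_train(0.5), lfp(rep(pi, 100), 100),
                              "peak", tolerance = pi)
  expect_true(df$on_target)
})

test_that("confusion matrix reproduces the hand-enumerated toy session", {
  # 6 Hz cosine, 1 s: 6 peaks, 6 troughs; events near 3 peaks and 1 trough
  x <- cosine_lfp(6, duration = 3)
  ph <- instantaneous_phase(x)
  ex <- phase_extrema(ph)
  pk <- ex$peak_times[ex$peak_times > 0.95 & ex$peak_times < 1.95][1:3]
  tr <- ex$trough_times[ex$trough_times > 0.95 & ex$trough_times < 1.95][1]
  ev <- event_train(sort(c(pk + 0.002, tr)))
  sub <- list(peak_times = ex$peak_times[ex$peak_times > 0.95 &
                                           ex$peak_times < 1.95],
              trough_times = ex$trough_times[ex$trough_times > 0.95 &
                                               ex$trough_times < 1.95])
  expect_length(sub$peak_times, 6)
  expect_length(sub$trough_times, 6)
  oracle <- brute_confusion(ev$times, sub, ph, "peak")
  cm <- phase_confusion_matrix(ev, sub, ph, "peak")
  expect_equal(cm$tpr, oracle$tpr)
  expect_equal(cm$tnr, oracle$tnr)
  expect_equal(cm$tpr, 3 / 6)
  expect_equal(cm$tnr, 5 / 6)
  # degenerate trains
  cm0 <- phase_confusion_matrix(event_train(numeric(0)), sub, ph, "peak")
  expect_equal(cm0$tpr, 0)
  expect_equal(cm0$tnr, 1)
  all_ev <- event_train(sort(c(sub$peak_times, sub$trough_times)))
  cm1 <- phase_confusion_matrix(all_ev, sub, ph, "peak")
  expect_equal(cm1$tpr, 1)
  expect_equal(cm1$tnr, 0)
  # zero extrema of a kind: undefined rate, not silently 0
  expect_warning(
    cmna <- phase_confusion_matrix(ev, list(peak_times = sub$peak_times,
                                            trough_times = numeric(0)),
                                   ph, "peak"),
    "undefined")
  expect_true(is.na(cmna$tnr))
})

test_that("confusion matrix equals the brute-force scan on random trains", {
  s <- quick_session(duration = 10, seed = 31)
  ph <- instantaneous_phase(s$signal)
  ex <- phase_extrema(ph)
  set.seed(99)
  for (i in 1:20) {
    n_ev <- sample(3:40, 1)
    # events snapped to the sample grid
    ev_t <- sort(sample(seq(0.5, 9.5, by = 1e-3), n_ev))
    ev <- event_train(ev_t)
    target <- sample(c("peak", "trough"), 1)
    oracle <- brute_confusion(ev_t, ex, ph, target)
    cm <- phase_confusion_matrix(ev, ex, ph, target)
    expect_identical(c(cm$n_inphase_stimulated, cm$n_outphase_stimulated),
                     c(oracle$n_in_hit, oracle$n_out_hit))
  }
})

test_that("swapping phase labels exchanges peak- and trough-target results", {
  s <- quick_session(duration = 15, seed = 12)
  ph <- instantaneous_phase(s$signal)
  ex <- phase_extrema(ph)
  cfg <- stim_config(mode = "peak", epoch_design = epoch_design("Stim", 15))
  ev <- run_closed_loop(s$signal, cfg)
  a <- phase_confusion_matrix(ev, ex, ph, "peak")
  b <- phase_confusion_matrix(ev, ex, ph, "trough", swap_phase_labels = TRUE)
  expect_equal(b$tpr, a$tpr)
  expect_equal(b$tnr, a$tnr)
  expect_identical(b$n_inphase_extrema, a$n_inphase_extrema)
})

test_that("fixed 20 Hz stimulation is phase-nonspecific on drifting theta", {
  s <- quick_session(duration = 120, seed = 17)
  ph <- instantaneous_phase(s$signal)
  ev <- run_fixed_frequency(epoch_design("Stim", 120), 20)
  cs <- classify_stimulations(ev, ph, "peak")
  # Rayleigh statistic below the 5% significance threshold
  n <- nrow(cs)
  z <- n * Mod(mean(exp(1i * cs$phase)))^2
  expect_lt(z, 3)                            # crit ~ -log(0.05) = 3.0
  h <- phase_histogram(ev, ph, n_bins = 20)
  expect_lt(max(h$fraction), 1 / 20 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("phase histograms conserve mass and localize concentrated events", {
  # all events at exactly phase 0: a single bin holds all mass
  flat0 <- lfp(rep(0, 300), 100)
  ev0 <- event_train(seq(0.2, 2.5, by = 0.1))
  h00 <- phase_histogram(ev0, flat0, n_bins = 20)
  expect_equal(max(h00$fraction), 1)
  expect_equal(sum(h00$fraction > 0), 1L)
  # events at the peaks of a cosine: mass concentrates around phase 0
  x <- cosine_lfp(6, duration = 3)
  ph <- instantaneous_phase(x)
  ex <- phase_extrema(ph)
  ev <- event_train(ex$peak_times[ex$peak_times > 0.5 & ex$peak_times < 2.5])
  h <- phase_histogram(ev, ph, n_bins = 20)
  expect_equal(sum(h$fraction), 1)
  near0 <- abs(h$mids) < 2 * pi / 20        # the two bins adjacent to 0
  expect_gte(sum(h$fraction[near0]), 0.99)
  # no events: flagged all-zero histogram
  h0 <- phase_histogram(event_train(numeric(0)), ph)
  expect_true(h0$empty)
  expect_true(all(h0$fraction == 0))
  expect_error(phase_histogram(ev, ph, n_bins = 2), "n_bins")
})
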