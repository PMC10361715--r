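---
title: "Closed-loop theta-phase stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop theta-phase stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetastim)
```

This vignette documents the models behind `thetastim`, the parameters that
matter, the numerical conventions used throughout, and the design choices
made where the underlying methodology left the design open.

## The synthetic session model

Every downstream stage is validated against simulated sessions with exact
ground truth, so the generator is first-class, tested code rather than a
fixture.

**Theta.** Hippocampal theta is quasi-periodic: its instantaneous frequency
wanders cycle by cycle within the 4–10 Hz band. We model this as a
per-cycle sinusoid: each cycle's frequency is an independent draw from a
Gaussian truncated to the band (defaults: mean 7 Hz, SD 1 Hz, bounds
4–10 Hz), and the phase advances continuously across cycle boundaries
(2π per cycle, starting at a peak at t = 0). This is the simplest model
that produces realistic cycle-duration variability for a predictor to
track, while keeping analytic peak/trough times and an exact phase signal.
More structured dynamics (frequency autocorrelation, amplitude modulation,
asymmetric cycles) are deliberately out of scope.

**Background.** Broadband LFP background is spectrally shaped Gaussian
noise with amplitude ∝ f^(−α/2) (power 1/f^α, α = 1 by default), rescaled
to an exact standard deviation. No published amplitude statistics were
available for the recordings this emulates, so the default scale was
chosen once: theta amplitude 100 µV over 22.4 µV noise SD, i.e. a
signal-to-noise power ratio of 10 (≈ 10 dB) — a clean but not noiseless
recording. Both knobs are exposed (`theta_amp`, `noise_scale`).

**Coupled gamma.** `generate_pac_lfp()` adds a narrowband gamma component
whose instantaneous amplitude is

    gamma_amp * (1 + coupling_strength * cos(theta_phase − coupling_phase)),

so coupling strength 0 gives a flat envelope and strength 1 silences gamma
at the anti-preferred phase. The carrier defaults to band-limited filtered
noise rather than a pure tone: a noise carrier has realistic (Rayleigh-like)
envelope statistics, which is what modulation-index estimators actually
face; a `"sine"` carrier is available for analytic checks.

**Behavior.** Motion traces are generated directly (video tracking is out
of scope): per-frame motion jitters above a stillness threshold except
during requested bouts, where it jitters below it. The generating bout
list and threshold are embedded so freezing scoring can be verified
exactly at frame resolution.

What the generator does *not* emulate: movement artifacts, electrode
drift, non-stationary theta power, inter-regional phase offsets, and real
spike-field content. Tests passing on these simulations therefore
demonstrate algorithmic correctness and calibration under controlled
conditions, not robustness to every in vivo pathology.

## The causal predictor

The real-time path is strictly causal — the output at time t depends only
on samples at or before t (a property checked by truncation tests).

1. **Filtering.** A linear-phase FIR bandpass, default 4–10 Hz. The
   descriptions of this band in the source methodology vary between
   2–10, 4–10 and 4–12 Hz; the band is a configuration field and 4–10 Hz
   is the documented default. The FIR order is not specified anywhere;
   we default to 200 taps at 1 kHz. This choice balances two pressures:
   a longer filter separates theta from the 1/f background better, but
   its group delay (order/2 samples, exactly known for a symmetric FIR)
   pushes the stimulation horizon further into the future. At 200 taps
   the delay is 100 ms, which keeps the prediction horizon within a
   single theta cycle for virtually all cycle frequencies in the band.
2. **Extremum confirmation.** A turning point of the filtered signal is
   confirmed when the sign change of its first difference is sustained for
   at least 3 samples — a noise-robustness rule with 3 ms confirmation
   latency at 1 kHz. Alternation is enforced: a same-kind candidate
   replaces the previous extremum only if more extreme, and an
   opposite-kind candidate must arrive at least a quarter of the shortest
   passband period (25 ms at 10 Hz) after the previous extremum.
3. **Prediction.** The next target extremum is predicted at the last
   target-kind extremum plus the mean of the most recent `n_cycles_avg`
   same-kind cycle durations (default 3 — enough to suppress single-cycle
   jitter while still tracking drift). Predictions are made in
   filtered-signal time and mapped back to input time by subtracting the
   constant group delay; a prediction that is not in the future is
   advanced by whole mean cycles until it is.
4. **Emission.** A TTL is emitted at the predicted time if it falls inside
   a Stim epoch and at least one refractory period (default 50 ms, half
   the shortest theta period) after the previous event. A newer prediction
   supersedes a pending, unfired one.

Fixed-frequency controls (`run_fixed_frequency()`) tile each Stim epoch
with events at exact 1/rate spacing from the epoch onset.

## Phase evaluation

Post-hoc phase is computed the standard way: zero-phase (forward–backward)
fourth-order Butterworth, 4–10 Hz, then the Hilbert analytic-signal
argument. The package-wide convention is peak = 0, trough = ±π, wrap to
(−π, π]. The evaluation filter is deliberately different from the causal
FIR: evaluation may use the whole recording, the stimulator may not.

The on-target criterion is a **phase** window, ±π/4 (a quarter cycle)
about the target phase — not a time window — so it is invariant to cycle
frequency. A phase error of exactly π/4 counts as on-target (documented
tie-break). Sensitivity counts *extrema whose window contains at least one
event*, not raw events, so TPR is bounded by 1 even for 20 Hz trains;
specificity counts out-of-phase extrema with no event in their window.
Event/extremum pairing uses the unwrapped phase, giving every theta cycle
its own phase coordinate. When the electrode sits below the theta phase
reversal (e.g. in the dentate gyrus rather than CA1), `swap_phase_labels`
rotates the phase by π and exchanges peak/trough extrema, which exactly
swaps peak- and trough-target results.

Rates are reported as `NA` with a warning — never silently zero — when a
session contains no extrema of the required kind.

## Spectral estimation

Preprocessing: mean removal, 1–100 Hz fourth-order Butterworth bandpass,
and a fourth-order band-stop of ±2 Hz around 60 Hz, all zero-phase.

Spectrograms use nine Slepian tapers on 5 s windows. The time–bandwidth
product follows the standard (K + 1)/2 sizing for K tapers (NW = 5). The
stated "1 s overlap" is read literally, giving a 4 s step; a different
step is available via the `overlap` argument for users who intend a 1 s
step instead. Slepian sequences are computed from the symmetric
tridiagonal eigenproblem; for windows longer than 513 samples the
eigenvectors are computed on a 513-point grid, spline-interpolated to full
length, and renormalized to unit energy — the approximation error is far
below multitaper estimator variance, and tapers are cached per
(length, NW, K). One-sided spectra are scaled to power per Hz, so the
integrated PSD matches the signal variance (verified via a Parseval test
at 5% tolerance).

State-split PSDs (`psd_by_state()`) estimate freezing and non-freezing
spectra on contiguous same-state segments only — windows never straddle a
state boundary — skipping and counting segments shorter than one window.

## Phase-amplitude coupling

The modulation index bins gamma amplitude into twenty 18° theta-phase
bins (half-open [left, right) intervals, last bin closed — an exact
partition of the circle), normalizes the per-bin means to a distribution
P, and reports the KL divergence from uniform divided by log 20. Empty
bins contribute 0 (0·log 0 := 0) and are flagged; an all-zero amplitude
yields an undefined (`NA`) MI. MI is invariant to amplitude rescaling and
bounded in [0, 1], both property-tested.

The MI theta band defaults to 4–10 Hz (the procedural definition); the
narrower 4–8 Hz variant that appears in some result descriptions is
available by argument. Slow gamma is 35–55 Hz and mid gamma 55–85 Hz. By
default all samples of an epoch enter the MI; a per-sample `mask` argument
supports movement-only variants. Comodulograms scan phase bands of 4 Hz
width in 1 Hz steps and amplitude bands of 20 Hz width in 5 Hz steps;
cells that would cross the Nyquist frequency are `NA`, not zero. The
preferred phase is the circular mean of bin centers weighted by P, with an
explicit undefined-direction signal for uniform or antipodally balanced
distributions.

## Behavior and statistics

Freezing requires ≥ 6 s of sub-threshold motion, boundary inclusive;
shorter stillness runs are discarded entirely. The motion threshold is
per-session configuration, mirroring per-animal manual tuning. Per-epoch
percentages use the four-epoch No Stim/Stim/No Stim/Stim design (180 s
epochs). Light-induced freezing is computed as stimulation minus the
preceding baseline, `((e2 − e1) + (e4 − e3)) / 2`, so that positive values
mean stimulation increased freezing; the phrasing that subtracts in the
opposite order appears in one figure legend, and the sign choice here is a
documented decision consistent with positive reported effects. Subjects
are included when light-induced freezing reached ≥ 5 percentage points on
≥ 2 of 4 experiment days.

`compare_groups()` reports Shapiro–Wilk and Levene diagnostics alongside a
paired or independent t-test (pooled variance unless Levene rejects
equality) and applies the Bonferroni correction
`p_adj = min(1, p · n_comparisons)`. Diagnostics are reported rather than
used to switch to nonparametric tests, matching a protocol in which the
data were established as normal. The MI-vs-freezing association uses
Pearson correlation by default (linear fits are the usual presentation),
with Spearman as an option, and returns both an all-animals variant and a
responders-only variant (light-induced freezing > 0).

## Problem sizes and runtime

The test-suite and acceptance workloads were sized for a desktop run:
ten 180 s sessions at 1 kHz (~12 000 pooled extrema per targeting mode)
for closed-loop evaluation; 120 s sessions for comodulogram recovery
across five seeds; 10 s toy sessions for the 100-train brute-force
equivalence check. At these sizes the full suite runs in ~2.5 minutes and
the acceptance script in ~1 minute on one CPU.

## Known limitations

- The predictor emulation is sample-synchronous and ignores hardware
  latencies (DAC, laser rise time); it models algorithmic, not platform,
  performance.
- The synthetic theta model draws cycle frequencies independently;
  rhythms with strong frequency autocorrelation would favor longer
  `n_cycles_avg` than the default.
- The modulation index shares the known biases of binned KL estimators:
  it grows with recording length for finite samples and is not comparable
  across different bin counts.
- Group statistics operate on per-animal summaries; no mixed-effects
  modeling across days or epochs is provided.
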