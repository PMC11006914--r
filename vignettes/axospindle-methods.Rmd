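---
title: "Methods: spindle oscillations and conduction delays in single axons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle oscillations and conduction delays in single axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In a reconstituted hippocampal network, neurons from the four subregions of
the hippocampal formation (EC, DG, CA3, CA1) grow in separate compartments
connected by microfluidic tunnels so narrow (3 x 10 x 400 um) that only axons
enter them. Two electrodes 200 um apart inside a tunnel record the same axon
twice, which turns two classical population measurements into single-axon
measurements: the conduction delay of an event between the electrodes gives
its propagation velocity along one axon, and the tunnel's high impedance
shields the electrodes from volume-conducted field potentials, so any slow
oscillation seen there reflects the axon's own membrane potential.

`axospindle` implements the full analysis chain for such recordings:
detection of 10-16 Hz spindle oscillations and 0.5-4 Hz slow waves, spike
detection with cross-electrode matching, conduction-delay and velocity
estimation for both spikes and slow waves, quantification of spindle nesting
within slow oscillations, spike-phase coupling statistics, inter-channel
spindle-envelope correlations, and log-normal characterization of event
metrics. A synthetic-recording generator with exact ground truth stands in
for raw data so that every stage is testable end to end.

## Signal conditioning

Raw data are 25 kHz voltage traces in microvolts. The LFP used for spindle
work is obtained by decimation to 1 kHz. Decimation is performed in two
stages (25 kHz -> 5 kHz -> 1 kHz), each stage a 50th-order Kaiser-window FIR
low-pass (cutoffs 1000 Hz and 200 Hz, beta = 5) applied with its group delay
compensated, followed by keeping every 5th sample. A single 51-tap FIR at
25 kHz cannot both preserve the LFP band and attenuate content near the
1 kHz Nyquist (its frequency resolution is about 500 Hz); splitting the
factor-25 decimation into two factor-5 stages keeps the same filter order
per stage while achieving unity gain (within 0.1%) below 20 Hz and about
-55 dB at 400 Hz. DC gain is exactly 1.

Band filters follow conventional electrophysiology designs:

* spindle band: 6th-order Butterworth high-pass at 8 Hz cascaded with an
  8th-order Butterworth low-pass at 16 Hz, at 1 kHz;
* spike band: 4th-order elliptic band-pass 300-3000 Hz (0.1 dB ripple,
  40 dB stopband) at 25 kHz.

All IIR filters are applied forward-backward (zero-phase) by default. The
events this package times — spindle onsets, slow-wave troughs, spike peaks —
are compared *across channels* at sub-millisecond resolution, and a causal
filter's group delay (tens of milliseconds in the spindle band) would dwarf
the effects of interest; zero-phase application makes the filtering
transparent to event timing. Causal application remains selectable
(`zero_phase = FALSE`).

Envelope and instantaneous phase come from the analytic signal (FFT
half-spectrum construction). The phase convention places 0 degrees at the
positive-going zero crossing, 90 at the oscillation peak and 270 at the
trough; all phase histograms use 50 bins over [0, 360). Time-frequency maps
use a generalized Morse wavelet with symmetry 3 and time-bandwidth product
60 (the product interpretation, giving beta = 20); wavelets are
peak-normalized so a pure tone's scalogram ridge sits at the tone frequency.

## Spindle detection

A 1 kHz channel is spindle-band filtered and its Hilbert envelope computed.
A window is a spindle when the envelope stays above mean + 1.5 SD
continuously for more than 300 ms and exceeds mean + 2.5 SD at least once
inside the window; boundaries are the 1.5 SD crossings, and events closer
than 500 ms are merged (metrics recomputed over the merged span). Mean and
SD are those of the whole channel's envelope — the recordings are short
(5 min) and stationary by design, so per-epoch baselines add variance
without benefit. Two thresholds in the channel's own envelope units make
detection scale-equivariant: rescaling a channel leaves event times
unchanged.

Per event we report duration, area under the envelope (trapezoidal), the
amplitude area/duration, the envelope peak, and the inter-spindle interval
(next start minus this end). Events shorter than 0.4 s stay in the event
table but are flagged and excluded from distribution statistics, as are
channels with fewer than two spindles in the recording.

## Slow waves and conduction delays

Two distinct slow-wave views serve two purposes:

* **Trough timing** (for cross-electrode delays) runs at the raw 25 kHz
  rate on a 50 Hz zero-phase low-passed copy, because the delays of
  interest (0.3-1.5 ms) are unresolvable at 1 kHz. A local minimum is a
  trough when inter-trough spacing is at least 100 ms, its depth is at
  least 20% of the channel's deepest excursion, at most -100 uV, and its
  width at half-prominence is at least 4 ms (which rejects spikes).
* **Slow-oscillation epochs** (for nesting) are peak -> positive-to-negative
  crossing -> trough triplets of the mean-subtracted, 4 Hz zero-phase
  low-passed trace; epochs whose peak and trough both rank in the top 40%
  of their distributions are retained (ties kept). A high-pass was
  deliberately avoided here: at 0.1 Hz its forward-backward transient spans
  several seconds and distorts the amplitude ranking near the record edges.
  On continuous recordings an optional trough floor (the same -100 uV
  slow-wave criterion; used by the pipeline) keeps micro-noise zero
  crossings out of the ranking.

Troughs from the two electrodes of a tunnel are paired greedily by minimum
absolute time difference, one use per trough, capped at 5 ms; spikes are
matched the same way with a 2 ms cap (wide enough for 0.1-0.6 m/s over
200 um; the matching window is not a published value and is exposed as an
argument). Signed spike delays are histogrammed at 0.04 ms (one sample);
peaks of the 3-bin-smoothed histogram identify putative axons, the sign of
the modal delay gives the conduction direction, and member delays within
0.2 ms of the mode give the per-axon mean and SE. An axon whose delay SE
exceeds its mean, or whose SE is zero, is excluded. Velocity is
spacing/delay, reported to two significant figures, and the percent-slower
comparison between slow-wave and spike velocities is computed from the
velocities rounded to two decimals so that the arithmetic matches values
as printed.

## Nesting and the log-log lag fit

Each spindle is assigned the slow-oscillation peak that directly precedes
its envelope peak; the lag between the two is the nesting lag (spindles with
no preceding slow oscillation are dropped and counted). The peak-to-peak
reference is used rather than onset-to-onset; onset-based lags are obtainable
by passing event onset times instead. Lags are histogrammed on 50 log-spaced
bins, and log10(count) is regressed on log10(bin center) above a short-time
boundary; the boundary is grid-searched over the bin left edges within
[0.001, 0.5] s and the best-R^2 candidate returned. Empty bins are skipped
rather than floor-imputed — imputation would bias the slope systematically.
For lags drawn from a power law p(t) ~ t^-alpha, log-binned counts scale as
t^(1-alpha), so the fitted slope estimates -(alpha - 1). The grid is the bin
edges themselves (the histogram cannot distinguish boundaries inside one
bin), so boundary resolution is one log-bin.

## Phase coupling and envelope correlations

Spikes falling inside spindle windows get the instantaneous phase of the
10-16 Hz filtered trace at their peak time. Non-uniformity is tested with
the Hodges-Ajne omnibus statistic m (the minimum count over all
half-circles): exact tail probability (n - 2m) C(n, m) 2^(1-n) for
n <= 50, the Ajne normal-form approximation above (and p = 1 when
n = 2m). The published effect size — largest minus smallest pooled bin
count divided by the across-recording SD of the normalized bin counts — is
implemented as stated, but its definition is ambiguous in prose, so the
resultant vector length is always reported alongside as the standard
measure.

Envelope correlations zero each channel's envelope outside its own spindle
windows, then evaluate the coefficient-normalized cross-correlation over
lags up to 0.1 s and return the peak and its lag. Normalization is by total
energy (peak autocorrelation = 1), which is the behaviour of coefficient
cross-correlation on zero-masked signals; negative coefficients are possible
and reported. With a known inter-electrode path, distance over the peak lag
bounds the propagation velocity from below. Group comparisons (correlations
or log-transformed event metrics across connections) use one-way ANOVA with
Tukey's HSD.

## The synthetic generator

`generate_recording()` builds, per tunnel, two 25 kHz channels with exact
ground truth:

* Gaussian background noise (default SD 10 uV);
* biphasic spikes (1.2 ms template, negative-first) at Poisson times with a
  3 ms refractory gap;
* slow oscillations at Poisson times, each a single Gabor cycle — a 2 Hz
  carrier under a 0.15 s Gaussian envelope — with log-normal amplitudes
  (median 800 uV, sigma 0.12 in log10). The Gabor shape was chosen over
  piecewise half-cosines because the latter's derivative kinks leak tens of
  microvolts into the 8-16 Hz band at slow-wave amplitudes, contaminating
  the spindle envelope; the Gabor is spectrally confined to the slow band
  while preserving the peak/crossing/trough epoch structure;
* spindle bursts — a carrier at 12 Hz under a Gaussian envelope whose FWHM
  is the log-normally drawn duration (mode 0.65 s), carrier peak aligned
  with the envelope peak so the 90-degrees-at-peak convention holds
  exactly — nested after slow oscillations whose amplitude ranks in the top
  40%, at power-law lags (alpha = 1.5 on [0.05, 1.5] s). The generator
  resamples any draw that would put another slow oscillation between the
  nesting one and the spindle, or two spindles within 1 s of each other, so
  the drawn lags are exactly the lags a correct analysis should measure;
* the second electrode carries the same event streams shifted by the spike
  and slow-wave delays, rounded to integer 25 kHz samples (the rounded
  value is the recorded truth), with independent noise;
* optionally, in-spindle spikes are drawn with von Mises phase locking
  (Best-Fisher sampler) around the carrier peak.

The reference configuration (`preset_paper_like()`) uses four tunnels
(EC->DG feed-forward, DG->CA3 feedback, CA3->CA1 feed-forward, CA1->EC
feedback), 300 s at 25 kHz, spike delay 0.40 ms (0.5 m/s over 200 um),
slow-wave delay 0.86 ms (0.23 m/s), 10 spindles/min of mode duration
0.65 s — values inside the reported physiological ranges. The spindle
amplitude law is deliberately tight (median 60 uV, sigma 0.05 in log10):
because the detector thresholds at 2.5 SD of the *whole-channel* envelope,
the channel SD at realistic spindle densities is dominated by the spindles
themselves, and a broad amplitude law would place a fraction of injected
events below their own detection threshold by construction. The preset is a
ground-truth recovery benchmark, so its events are kept unambiguously
supra-threshold; realism of broad amplitude distributions is exercised
separately in the distribution-fitting module.

What the generator does *not* emulate: spike waveform diversity and
multi-axon tunnels (one axon per tunnel; multimodal delay histograms are
exercised with constructed trains instead), bursting and rate
non-stationarity, electrode drift, line noise, and correlated (1/f)
background. Passing the recovery tests therefore demonstrates correctness
of the analysis chain under the stated event model, not robustness to every
pathology of real MEA data.

## Numerical choices and degenerate inputs

* Intervals are half-open [start, end); times are seconds,
  t = t0 + index/rate with 0-based indices; event times at 25 kHz
  resolution for spikes and troughs, 1 kHz for spindles.
* Noise SD for spike thresholds is the plain standard deviation of the
  spike-band trace; a median-based robust estimator is selectable.
* Greedy event matching ranks candidate pairs globally by |dt| (ties by
  time), so pairing is order-independent and symmetric under electrode
  swap up to delay sign.
* Flat signals: spike detection errors (SD = 0); spindle detection returns
  no events; trough detection returns an empty table.
* All-equal samples: the log-normal fit returns a flagged degenerate mode;
  the log-log lag fit raises an error.
* Zero-variance groups: ANOVA is reported as undefined with a notice
  rather than NaN propagation; the paired attenuation t-test reports p = 1
  (no decline) or ~0 (deterministic decline).
* The two-component log-histogram fit is retained only when it improves
  R^2 by more than 0.02 over one component; Gaussian fits to binned
  probabilities use unweighted least squares (Levenberg-Marquardt), seeded
  from the two dominant smoothed histogram maxima.

## Problem sizes

The test suite and the acceptance script regenerate all inputs from code:
the full study-condition preset (300 s x 8 channels at 25 kHz) once, shorter
(60-120 s) single-tunnel recordings for focused properties, 10^5-draw
samples for distribution fits, 5000-lag samples for the nesting fit, and
1000 replicates of n = 10^4 for the omnibus-test calibration. These sizes
keep every statistical tolerance comfortably powered while the entire suite
remains a few minutes of compute.

## Known limitations

* The 1 kHz envelope quantizes envelope-correlation lags to 1 ms, so the
  sub-millisecond slow-wave delay appears there as a 0-1 ms lag; use the
  trough-based estimator for sub-sample delays.
* The normalized matching index is a reconstruction (matched fraction per
  electrode); the original definition lives in prior work and is not
  reproduced verbatim.
* Spike sorting is deliberately absent: tunnels are treated as
  single-cluster sources, and multi-axon tunnels are resolved only through
  multimodal delay histograms.
* The "unscaled for other subregions" branch of the published correlation
  normalization is ambiguous and not implemented; only coefficient
  normalization is provided.
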