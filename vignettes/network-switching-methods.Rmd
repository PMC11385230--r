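---
title: "Methods: antagonistic network dynamics from intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antagonistic network dynamics from intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When attention switches between externally oriented processing (e.g. visual
search) and internally oriented processing (e.g. autobiographical memory),
two large-scale brain networks — the default mode network (DMN) and the
dorsal attention network (DAN) — exchange roles: one activates while the
other deactivates. In intracranial EEG (iEEG), network activation is
visible as a broadband power redistribution: high-gamma power (HGB,
52–120 Hz, a proxy for local population firing) rises while low-frequency
power (delta through beta) falls, and vice versa for deactivation.

`ieegswitch` implements the full analysis chain for this phenomenon:

1. **Preprocessing** — nearest-neighbor bipolar referencing along each
   electrode shank, zero-phase Butterworth high-pass (0.1 Hz) and notch
   (48–52, 98–102 Hz) filtering, integer-factor downsampling to 512 Hz,
   extraction of switch trials `D(t, ch, tr_c)` spanning −4…4 s around
   the switch (t = 0), and amplitude-based epoch rejection (±6 SD with
   100 ms margins; whole trials are never dropped).
2. **Localization** — assignment of bipolar channel midpoints (MNI mm) to
   atlas labels, with a 10 mm (inclusive) tolerance to the nearest
   labeled voxel center.
3. **Relative band power (RBP)** — sliding Hann-windowed periodograms
   stepped every 31.25 ms with band-dependent window lengths (2 s for
   delta, 1 s for theta, 0.5 s otherwise), dB transform, z-scoring of
   every frequency bin over the whole recording session (which removes the
   1/f background), and averaging into six bands: delta 0.1–3, theta 4–7,
   alpha 8–12, beta 13–30, low-gamma 31–48 and HGB 52–120 Hz (bins in the
   notched ranges never enter the HGB). A constant-Q Morlet wavelet
   estimator (6 cycles) provides an independent spectral route on the
   same time grid with the same normalization.
4. **Statistics** — a per-channel condition-difference strength (an
   SNR-type ratio), channel-level Wilcoxon rank-sum tests per time step
   with joint Benjamini–Hochberg FDR (α = 0.05) and a temporal-continuity
   screen (runs strictly longer than 100 ms), network-level tests across
   channels (α = 0.001), and crossover-timing estimation.
5. **Connectivity** — time-resolved directed connectivity (DTF, PDC,
   Granger–Geweke causality) from sliding-window MVAR models, and the
   phase-locking value (PLV) from 2 Hz narrow-band Hilbert phases, with
   network-pair averaging and across-subject statistics.
6. **Synthetic cohorts** — a generator that plants every structure the
   analysis assumes, with exact ground truth for recovery testing.

## Key quantities

**SNR-type difference strength.** For each time step, band and channel,

$$\mathrm{SNR}(t, fb, ch) = \frac{\operatorname{var}_c\!\big[\operatorname{mean}_{tr}(\mathrm{RBP})\big]}{\operatorname{mean}_c\!\big[\operatorname{var}_{tr}(\mathrm{RBP})\big]},$$

summarized per (band, channel) as \(10\log_{10}\) of the time mean over
the analysis crop (−2.3…2.3 s). Both variances use the sample convention
(denominator \(n-1\)); with two conditions the numerator is
\((m_1 - m_2)^2/2\). This choice is flagged because a population-variance
convention would halve the numerator. A zero numerator maps to a −120 dB
sentinel; zero trial variance in both conditions is reported missing.

**Crossover time.** Per significant channel and band, the condition-common
response (mean across both conditions) is subtracted, both residuals are
low-pass filtered at 1 Hz (zero phase, order 6) on the 32 Hz band-power
grid, and the first sign change of their difference inside −0.5…2.0 s is
located with linear interpolation between the bracketing steps. Multiple
crossings return the first; no crossing returns none.

**Directed connectivity.** Trials are z-scored in the temporal domain,
band-split into 0.1–30, 31–48, 52–98 and 102–120 Hz (zero-phase
Butterworth), and an MVAR model
\(X(t) = \sum_{l=1}^{p} A(l)\,X(t-l) + E(t)\)
is fit by ordinary least squares in 500 ms windows stepped 125 ms,
pooling all trials of a condition as independent realizations (lagged
predictors never cross trial boundaries). The default order per band is
the integer bandwidth (29, 17, 46, 18); the order is not critical and can
be overridden. From \(\bar{A}(f) = I - \sum_l A(l) e^{-i 2 \pi f l / f_s}\)
and \(H(f) = \bar{A}(f)^{-1}\):

- DTF: \(|H_{mn}|/\sqrt{\sum_j |H_{mj}|^2}\) (inflow-normalized; rows of
  squares sum to 1),
- PDC: \(|\bar{A}_{mn}|/\sqrt{\bar{A}_n^* \bar{A}_n}\) (outflow-normalized;
  columns of squares sum to 1),
- GGC: \((Z_{nn} - Z_{mn}^2/Z_{mm})\,|H_{mn}|^2 / |S_{mm}|\) with
  \(S = H Z H^*\), computed from the full multivariate model.

Measures are evaluated on a 1 Hz grid inside each fitted band, z-scored
along time per (pair, frequency, condition), averaged into the six
analysis bands, and averaged over all directed channel pairs between the
two networks.

**PLV.** Signals are decomposed into 2 Hz non-overlapping bands
(0–120 Hz), instantaneous phases extracted by Hilbert transform over the
full −4…4 s epoch (the ±2.3 s crop discards the edges), and
\( \mathrm{PLV} = \frac{1}{N}\big|\sum_{tr} e^{i(\varphi_m - \varphi_n)}\big| \)
computed across the N trials of each condition. For independent channels
the Rayleigh expectation is \(\sqrt{\pi}/(2\sqrt{N})\) (≈ 0.114 at
N = 60), which the tests verify.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes:
512 Hz sampling, 60 trials per switching condition laid out in one
continuous session (trials of the two conditions alternate, spaced so the
−4…4 s epochs never overlap, onsets snapped to the 31.25 ms band-power
grid), a 1/f background (spectrally shaped Gaussian noise, default
exponent 1), and one band-limited oscillation per analysis band realized
as narrow-band-filtered Gaussian noise — not pure sinusoids — so MVAR
fitting stays well-posed.

Each oscillation's amplitude envelope carries the condition effect: the
multiplier is \(1 + s_c \cdot \gamma \cdot L(t - t_\times)\), where
\(s_c = \pm 1\) for the two conditions, \(\gamma\) is the condition
contrast (defaults 1.0–1.2), \(L\) is a logistic step from −½ to +½ with
0.3 s transition width, and \(t_\times\) is the planted crossover time
(defaults inside the −0.5…2.0 s search window; group NetB can lag NetA by
a configurable offset). Because a monotone amplitude transform cannot move
the point where the two conditions' envelopes are equal, the band-power
crossover of the z-scored RBP occurs exactly at \(t_\times\), making the
crossover estimator testable against ground truth.

**Cross-group coupling** is a lagged linear mixing term: the driver
group's mean signal is band-limited with a *causal* AR(2) resonator and
added, delayed by the configured number of samples, to the driven group's
channels (optionally reversing direction at t = 0 in every trial). The
causality of the resonator matters: band-limiting the driver with the
package's zero-phase filter would mix the driver's future into the driven
channels and erase the planted direction — we verified that directed
measures then fail to recover it. With the causal driver, DTF/PDC/GGC
recover the direction essentially always at the default strength.

An `"ar"` mode replaces the envelope construction with band-limited AR(2)
oscillators — one per band, pole radius chosen so the resonance bandwidth
equals half the band width, keeping each oscillator's spectral support
inside its band — whose innovation amplitude follows a slow, trial-locked
log-normal envelope (`exp(0.4 sin(2πt/4 + φ))`, i.e. sinusoidal
log-power with a 4 s period, matching the lognormal character of cortical
band-power fluctuations). This is the regime in which MVAR model spectra
should, and do, reproduce the STFT band power; agreement is tightest in
the fast bands, while the delta and theta bands are bounded by the
resolution mismatch between their long spectral windows (2 s, 1 s) and
the 500 ms MVAR window.

Contacts are laid out so that nearest-neighbor bipolar referencing
recovers exactly one planted channel per adjacent pair while cancelling a
shared reference signal (each deeper contact adds one channel signal on
top of its shallower neighbor). Rare rectangular artifacts of configurable
amplitude (in channel-SD multiples) and duration are injected at Poisson
onsets and logged. Determinism: each subject draws from its own RNG
stream derived from the master seed, so cohorts are bit-reproducible and
subject-level parallelism would not change results.

**What the generator does not emulate:** epileptiform spike morphology,
volume conduction and realistic head geometry, non-stationary background
(e.g. sleep/vigilance drifts), and inter-subject variability in electrode
coverage. Passing recovery tests therefore demonstrates correctness of
the estimators under the planted model, not robustness to every artifact
of clinical recordings.

## Numerical choices

- **Zero-phase filtering** is applied spectrally: the forward–backward
  Butterworth magnitude response \(|H(f)|^2\) multiplies the FFT of the
  reflect-padded, mean-removed signal (the DC pedestal is handled
  analytically by the gain at f = 0). This equals the steady-state
  response of `filtfilt` while remaining stable at the 0.1 Hz/512 Hz
  relative cutoff, where transfer-function polynomial filtering is
  numerically unusable. Cascaded filters multiply their gains in a single
  transform round.
- **dB floor**: power is dB-transformed as
  `10*log10(p + 1e-12 * median(p))`, keeping silent fixtures finite.
- **STFT grid**: window centers lie on multiples of the 31.25 ms step
  from the session start for every window length, so band tensors from
  different window groups concatenate exactly; no zero padding — edge
  windows that would overrun the session are simply not computed (the
  analysis crops to ±2.3 s anyway).
- **Morlet path**: constant-Q, 6 cycles, center frequencies on each STFT
  bin grid; implemented in the frequency domain with a fold-decimate
  inverse FFT (power is only needed every 16 samples). It runs on the
  continuous session so it shares the session z-scoring contract with the
  STFT path.
- **MVAR fitting**: normal equations solved by Cholesky with a tiny
  relative ridge escalated from 0 to at most 1e-6 of the mean diagonal —
  band-limited trials make the lagged design ill-conditioned, and the
  ridge selects the minimum-norm solution on the degenerate subspace
  without measurably biasing well-posed fits (VAR recovery RMSE < 0.05 in
  tests).
- **Rank-sum tests** use a vectorized normal approximation with tie and
  continuity corrections (exact null distribution below n = 10 without
  ties); the channel-level pipeline runs ~10^4 tests per subject, so
  per-test calls to `wilcox.test` would dominate runtime. Agreement with
  `wilcox.test` and with a permutation oracle is tested.
- **Continuity rule**: "longer than 100 ms" is strict — at the 31.25 ms
  step a run must have ≥ 4 consecutive significant steps (125 ms);
  3 steps (93.75 ms) are removed.
- **Crossover interpolation** is linear between the two bracketing steps;
  ties at exactly zero return the earlier step.
- **Atlas assignment**: Euclidean distance in mm world space, midpoint to
  labeled-voxel center; ≤ 10 mm inclusive; exact distance ties between
  two labels are conservatively unassigned with a warning.

## Open design points and how they were resolved

- The session z-score factors μ(f, ch), σ(f, ch) are computed per
  recording session (not pooled across sessions), matching their
  definition over "the entire recording session".
- Channel-level FDR is applied before the 100 ms continuity screen,
  matching the order in which the procedure is described.
- The SNR summary averages the ratio over time first and then takes
  10·log10 (log of the time mean).
- PDC uses \(\bar{A}(f) = I - \sum_l A(l)e^{-i2\pi fl/f_s}\), the standard
  convention, which yields the identity pattern for A = 0.
- Trial z-scoring precedes band-split filtering.
- The 10 mm assignment tolerance is applied uniformly to all channels.

## Validation studies (run by tests and `scripts/acceptance.R`)

- **Estimator agreement**: on a 20-channel cohort with 60 trials per
  condition and smooth planted modulations in all six bands, the mean
  Pearson correlation between STFT and wavelet band-power time courses
  (per band, condition and channel group) must be ≥ 0.90.
- **MVAR spectral fidelity**: on AR-mode cohorts, band power implied by
  the sliding-window model spectra must correlate ≥ 0.95 with the STFT
  band power across bands and groups.
- **Crossover-lag recovery**: planting HGB crossovers at 0.5 s (NetA) and
  0.72 s (NetB) — a 220 ms lag — across 20 cohorts of 10 + 10 channels,
  the recovered mean between-group difference must land within ±60 ms.
- **Exact invariants**: DTF row and PDC column normalization at machine
  precision; identity patterns for A = 0; PLV self-pair = 1; BH-FDR equal
  to a brute-force step-up oracle.
- **Direction recovery**: unidirectional VAR coupling recovered by all
  three directed measures in ≥ 95% of 50 simulations; with coupling
  reversal at t = 0 the two directional network series cross within ±3
  window steps of zero.
- **Error control**: on null cohorts (planted oscillations, zero
  contrast) the significant-channel fraction after FDR + continuity stays
  below 1% and network masks are empty at α = 0.001 in ≥ 95% of seeds;
  null PLV matches the Rayleigh expectation within 10%.
- **Rejection correctness**: ≥ 99% of planted high-amplitude artifact
  samples inside trials are masked, with mask extent equal to the
  artifact duration plus two 100 ms margins (±1 sample).

Problem sizes in the suite follow these stated conditions (20 channels,
60 trials per condition, 20 seeds where applicable); smaller cohorts are
used only in unit tests of individual operations.

## Known limitations

- The spectral route to zero-phase filtering reproduces `filtfilt`
  steady-state behavior but treats edges by reflection; epochs should be
  cut generously around the analysis window, as the pipeline does
  (−4…4 s epochs, ±2.3 s analysis crop).
- Directed measures are estimated from a closed system of the modeled
  channels; unmodeled common input can depress or inflate pairwise
  inflow ratios. This is inherent to MVAR connectivity.
- The generator's bipolar construction makes channel signals exactly
  recoverable; real bipolar montages mix neighboring sources.
- Network-level tests treat channels as exchangeable units within a
  network (as the underlying procedure does); no hierarchical
  subject-level model is fit.
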