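# ieegswitch

Antagonistic brain-network dynamics from intracranial EEG (iEEG) during
switching between externally and internally oriented attention.

When attention switches between an external task (e.g. visual search) and
an internal one (e.g. autobiographical memory), the default mode network
(DMN) and the dorsal attention network (DAN) exchange activation states:
high-gamma power (HGB, 52–120 Hz, a proxy for local population firing)
rises in the activating network while its low-frequency power (< 30 Hz)
falls, and the two networks' condition-specific band-power curves *cross
over* near the switch. `ieegswitch` is a tested, reusable implementation
of the full electrophysiological analysis of this phenomenon, for
researchers working with multichannel iEEG (or any multichannel
electrophysiology with event-locked condition structure).

## What it computes

- **Preprocessing**: nearest-neighbor bipolar referencing per electrode
  shank, zero-phase Butterworth high-pass (0.1 Hz) and notch filters
  (48–52, 98–102 Hz), integer downsampling to 512 Hz, trial extraction
  `D(t, ch, tr_c)` over −4…4 s around the switch, and ±6 SD amplitude
  epoch rejection with 100 ms margins.
- **Localization**: channel-midpoint assignment to atlas labels (NIfTI or
  in-memory volumes) with a 10 mm tolerance.
- **Relative band power (RBP)**: sliding Hann-windowed spectra stepped
  every 31.25 ms (2 s window for delta, 1 s for theta, 0.5 s otherwise),
  dB transform, per-bin z-scoring over the recording session
  (`(PSD − μ(f,ch)) / σ(f,ch)`), and averaging into six bands
  (delta…HGB). A 6-cycle Morlet wavelet estimator provides an
  independent route on the same grid.
- **Statistics**: condition-difference strength
  `SNR(t,fb,ch) = var_c[mean_tr RBP] / mean_c[var_tr RBP]` (summarized in
  dB over −2.3…2.3 s), channel- and network-level Wilcoxon rank-sum tests
  with Benjamini–Hochberg FDR (α = 0.05 / 0.001) and a > 100 ms
  temporal-continuity rule, and crossover-time estimation (common-mean
  subtraction, 1 Hz zero-phase low-pass, first crossing in −0.5…2.0 s).
- **Connectivity**: directed transfer function (DTF), partial directed
  coherence (PDC) and Granger–Geweke causality (GGC) from MVAR models
  `X(t) = Σ_l A(l) X(t−l) + E(t)` fit in 500 ms windows stepped 125 ms in
  four frequency bands, network-pair averaged and z-scored over time;
  plus the phase-locking value (PLV) from 2 Hz-band Hilbert phases.
- **Synthetic cohorts**: a generator planting 1/f background, band-limited
  oscillations with condition-dependent logistic power crossovers, lagged
  (optionally reversing) cross-group coupling and artifacts — with exact
  ground truth for recovery testing.

## Worked example

Generate one synthetic subject with planted band-power crossovers, run
the band-power and crossover stages, and compare against ground truth:

```r
library(ieegswitch)

cfg <- gen_config(n_subjects = 1, n_channels_per_network = 3,
                  n_trials_per_condition = 30, seed = 7)
cohort <- generate_cohort(cfg)

rec <- cohort$recordings[[1]]
bip <- filter_chain(bipolar_reference(rec))        # 6 bipolar channels
rbp <- epoch_rbp(session_rbp(bip), max_per_condition = 30)
sig <- channel_significance(rbp)                   # FDR + continuity
xo  <- crossover_map(rbp, sig$subjects[[1]]$sig_channel)
round(xo[c("alpha", "hgb"), ], 2)
#>       [,1] [,2] [,3] [,4] [,5] [,6]
#> alpha 0.58 0.58 0.60 0.61  0.6 0.61
#> hgb   0.50 0.49 0.49 0.51  0.5 0.50
```

The planted alpha crossover was 0.6 s and the planted HGB crossover
0.5 s (see `cohort$ground_truth`): each channel's recovered crossover
lands within a few tens of milliseconds of the planted time. `sig$R_C`
reports the fraction of channels significant in at least one band (1.0
here — every channel carries the planted effect), and
`rbp_snr(rbp)$snr_db` gives the per-band condition-difference strength in
dB (channel means 4.8–11.8 dB on this cohort).

Directed connectivity on a cohort whose coupling direction reverses at
the switch:

```r
bm <- data.frame(band = "alpha", lo = 8, hi = 12, amplitude = 0.9,
                 contrast = 0, crossover = 0.5, lag_netb = 0, width = 0.3)
cfg <- gen_config(1, 2, 40, band_modulations = bm,
                  coupling = list(band = c(8, 12), lag = 6,
                                  strength = 1.2, reversal = TRUE),
                  seed = 106)
tr <- extract_trials(filter_chain(bipolar_reference(
        generate_cohort(cfg)$recordings[[1]])), max_per_condition = 40)
sc <- sliding_connectivity(tr, list(NetA = 1:2, NetB = 3:4), "dtf",
                           fit_bands = mvar_fit_bands()[1, , drop = FALSE])
```

`sc$series[, "alpha", , ]` holds the z-scored network-averaged DTF for
the two directions: A→B dominates before t = 0, B→A after, and the two
curves cross within a window step or two of the switch.

## Package layout

- `R/synthgen.R` — cohort generator and artifact injection
- `R/preprocess.R` — referencing, filtering, epoching, rejection
- `R/localization.R` — atlas assignment (plus a synthetic atlas fixture)
- `R/spectral.R` — STFT/wavelet band power and normalization
- `R/stats.R` — SNR, rank-sum/FDR/continuity, crossover timing
- `R/connectivity.R` — MVAR, DTF/PDC/GGC, PLV, group statistics
- `R/pipeline.R`, `R/validate.R` — orchestration and recovery studies
- `vignettes/network-switching-methods.Rmd` — the methods vignette

See the methods vignette for the model, parameter and design rationale.
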