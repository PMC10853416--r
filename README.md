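# readspectra

Spectral band-power analysis and self-organizing-map classification of
reading EEG.

## What this package is for

Given multichannel EEG recorded while people read short literary texts of
three kinds — excerpts from a canonical novel, conventional fan fiction,
and deliberately badly written fan fiction ("badfiction") — the package
asks two questions:

1. does the spectral content of the EEG differ between text types, and at
   which channels and frequencies?
2. do habitual reader characteristics (reading frequency, literary-system
   familiarity, fantasy readership, fandom, attitude toward badfiction)
   modulate relative band powers?

It is aimed at cognitive-neuroscience and computational-literary-studies
workflows built on a 32-channel 10/10 montage at 500 Hz, with 150 stimuli
per participant (120 originals, 15 fanfictions, 15 badfictions). Because
such recordings are rarely redistributable, a synthetic-EEG generator with
injectable, known-truth effects makes every stage testable end-to-end.

## The statistics at the core

* **Spectra.** Stimuli are cut into 1-s Hamming windows every 0.5 s; the
  window-averaged periodogram (Welch normalization) gives the PSD
  $P(f)$ on a 1 Hz grid, 1–40 Hz. For band $b$ with bins $B_b$:
  absolute power $P_b = \mathrm{mean}_{f \in B_b} P(f)$, relative power
  $R_b = \sum_{B_b} P(f) \,/\, \sum_f P(f)$ (so $\sum_b R_b = 1$), and the
  brain rate $f_{BR} = \sum_b c_b R_b$ with $c_b$ the band centers
  (default edges: delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
  30–40 Hz).
* **Condition effects.** A permutation one-way ANOVA per
  (channel, frequency-bin) cell on within-participant condition means:
  $p = (1 + \#\{F^\pi \ge F_{obs}\})/(1 + n_\pi)$, Bonferroni over all
  cells.
* **Group effects.** For each (site, measure, variable) — 31 × 6 × 5 = 930
  cells in the full design — Levene and Shapiro–Wilk gate Student t /
  Welch t / Mann–Whitney U; Benjamini–Hochberg FDR over the pooled
  p-values; effect size as Cohen's
  $d = (\bar{x}_a - \bar{x}_b)/s_{\text{pooled}}$.
* **Classification.** A from-scratch Kohonen SOM (6 × 6 hexagonal grid,
  bubble neighborhood, 10,000 iterations,
  $w_c \leftarrow w_c + \alpha(t)(x - w_c)$) clusters stimulus-level
  spectra; majority-vote unit labels predict text type, evaluated on a
  participant-level 70/30 holdout via confusion matrix and per-class F1.

## Worked example

```r
library(readspectra)

spec <- design_spec(
  n_participants = 6, n_trials = 2, stimulus_duration_s = c(4, 6),
  effects = list(
    effect_spec("text_type", "badfiction", "beta", "absolute_scale", 0.5)),
  noise = noise_spec(pink_scale_uv = 1, blink_rate_hz = 0.1,
                     muscle_burst_rate_hz = 0, sensor_white_uv = 1),
  group_sizes = list(), seed = 7)

design <- generate_design(spec)
rec <- synthesize_recording(design$metadata[1, ], design$schedules[[1]], spec)
rec
#> <eeg_recording> participant P01: 32 ch x 51245 samples @ 500 Hz (102.5 s), 20 events

rec <- apply_bandlimit(rec)              # 0.5-40 Hz, zero phase
features <- spectral_features(rec)       # one row per (stimulus, channel)
round(colMeans(features[features$channel == "Pz",
  c("rel_delta", "rel_theta", "rel_alpha", "rel_beta", "rel_gamma",
    "brain_rate_hz")]), 3)
#>     rel_delta     rel_theta     rel_alpha      rel_beta     rel_gamma
#>         0.175         0.144         0.627         0.044         0.010
#> brain_rate_hz
#>         9.134
```

The parietal spectrum is alpha-dominated (63 % of power), as built into
the generator's resting topography, and the brain rate sits just above the
alpha lower edge. The injected badfiction effect — beta power halved — is
recovered from the measured features:

```r
feats <- do.call(rbind, lapply(seq_len(6), function(i)
  spectral_features(apply_bandlimit(
    synthesize_recording(design$metadata[i, ], design$schedules[[i]], spec)))))
beta <- tapply(feats$abs_beta, feats$text_type, mean)
round(beta / beta[["original"]], 2)
#> badfiction fanfiction   original
#>       0.55       1.00       1.00
```

(the 0.55 vs 0.50 gap is Hamming-window leakage from the unscaled
neighboring bands into the beta band edges). Classification metrics come
from `classification_report()`; on the held-out confusion counts
(134, 0, 1 / 0, 135, 0 / 0, 0, 135) it prints:

```r
classification_report(cm)
#> Confusion matrix (rows = true, columns = predicted):
#>            badfiction fanfiction original
#> badfiction        134          0        1
#> fanfiction          0        135        0
#> original            0          0      135
#>
#> Per-class F1: badfiction 0.996, fanfiction 1.000, original 0.996
#> Accuracy: 0.998
```

`run_pipeline(pipeline_config(...), out_dir)` chains all stages
(simulate → preprocess → features → stats → SOM) and writes TSV/JSON
artifacts plus a manifest with seeds and digests; `pipeline_report()`
prints the significant (channel, frequency) runs, the FDR-passing group
comparisons and the confusion matrix.

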