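---
title: "Spectral band-power analysis of reading EEG: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral band-power analysis of reading EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readspectra)
```

## The question and the pipeline

Can multichannel EEG distinguish which *kind* of literary text a person is
reading — excerpts from a canonical novel, conventional fan-written fiction,
or deliberately badly written fan fiction ("badfiction")? And do habitual
reader characteristics (reading frequency, familiarity with the literary
system, fantasy readership, fandom, attitude toward badfiction) modulate the
spectral content of the reading EEG?

`readspectra` implements the full analysis chain for a 32-channel, 500 Hz
reading study in which every participant reads 150 short stimuli (120
originals, 15 fanfictions, 15 badfictions, presented as 15 trials of the
pattern O-O-O-O-F-O-O-O-O-B):

1. **synthetic data** — a generator that emulates the study design with
   injectable, known-truth condition and group effects;
2. **preprocessing** — zero-phase IIR band-limiting to 0.5–40 Hz, automated
   noisy-channel rejection, ICA-based blink/muscle removal;
3. **spectral features** — overlapping 1-s Hamming windows, per-stimulus
   PSD, absolute and relative band powers, brain rate;
4. **group statistics** — permutation one-way ANOVA over the
   channel × frequency grid (Bonferroni), and a 31 × 6 × 5 cascade of
   two-group tests (Levene/Shapiro–Wilk gated t, Welch, Mann–Whitney) with
   Benjamini–Hochberg FDR and Cohen's *d*;
5. **classification** — a from-scratch Kohonen self-organizing map that
   predicts text type from stimulus-level spectra, with a participant-level
   70/30 holdout.

Because raw recordings of this kind are large and rarely redistributable,
every stage is exercised end-to-end against the generator: each synthetic
recording carries an analytic truth table (`truth_table()`) of the band
powers it was built from, so tests are parameter-recovery experiments
rather than golden-file comparisons.

## The synthetic-EEG model

A stimulus segment of duration $T$ is
$$x_c(t) = \sum_b \sqrt{P_{b,c}}\; \xi_{b}(t) + \text{pink}(t) +
  \text{white}(t) + \text{blinks}(t) + \text{bursts}(t),$$
where $\xi_b$ is unit-variance Gaussian noise band-limited to band $b$,
synthesized in the frequency domain and rescaled so the realized band
variance equals its target power $P_{b,c}$ *exactly* per segment — this is
what makes the truth table exact rather than asymptotic. The baseline
topography is a generic resting pattern (posterior-dominant alpha at
5–8 µV RMS, frontal delta/theta emphasis, weak beta/gamma), multiplied by
per-participant lognormal band factors (sd 0.08) drawn from a
per-participant substream, so adding participants never perturbs earlier
ones.

Injectable effects modify $P_{b,c}$ before synthesis: `absolute_scale`
multiplies a band's power; `relative_shift` adds a signed fraction to the
band's share and renormalizes the remaining bands at constant total power.
Artifacts emulate what preprocessing must remove: Poisson-scheduled blinks
(0.2 Hz, 80 µV raised-cosine pulses, frontal-dominant topography) and
muscle bursts (0.05 Hz, 15 µV, 25–45 Hz, temporal-dominant), over a
$1/f$ pink background (4 µV RMS) and 1.5 µV white sensor noise. These
rates/amplitudes are generic electrophysiology values chosen once for
realism; they are configuration, not estimates.

Stimulus durations are drawn uniformly from 8–15 s — a plausible silent
reading time for a 40-word text; no per-stimulus reading-time distribution
is available to emulate, so this is an explicit, configurable assumption.

What the generator does **not** model: volume conduction and channel
covariance structure, evoked (phase-locked) responses, non-stationarity
within a stimulus, realistic artifact morphology beyond band content and
topography. Passing recovery tests therefore demonstrates that the
*machinery* is correct and sensitive at realistic signal-to-noise ratios —
not that real reading EEG contains such effects.

## Preprocessing

**Band-limiting.** High-pass: Butterworth, order 6, cutoff 0.5 Hz
(transition ≈ 0.2 Hz). Low-pass: elliptic (Cauer), order 12, passband edge
40 Hz, 0.05 dB ripple, 60 dB stopband. The elliptic family is the design
choice that makes an order-12 filter actually "approximately zero from
41 Hz" while staying flat through 39 Hz — a Butterworth of that order has
a transition far too shallow to silence 45 Hz by 40 dB. Both filters run
forward and backward (zero phase, magnitude applied twice).

Numerically, both run as cascades of second-order sections: at 500 Hz a
0.5 Hz high-pass collapses to a transfer-function polynomial whose rounding
noise exceeds the signal, while biquads remain well conditioned. Each pass
uses odd-reflection padding plus per-section steady-state initial
conditions (computed in closed form from the biquad's pole pair), the
convention scipy's `filtfilt` uses. One consequence is shared by every
zero-phase IIR implementation: a tone that is non-zero at the recording
edge excites the slow (0.5 Hz) poles at the pad junctions, so the first and
last couple of seconds are a settling region. Stopband attenuation is
therefore specified — and tested — in the central, steady-state portion of
a long tone: DC and 45 Hz ≥ 40 dB down, 10 Hz within 5 %.

**Channel rejection** replaces manual inspection with a reproducible rule:
a channel is dropped when its variance exceeds the channel population
median by more than `z_threshold` (default 5) robust (MAD) standard
deviations. Rejected channels are dropped, not interpolated.

**ICA** is FastICA (tanh contrast, deflation) on whitened data, seeded and
deterministic. Component artifact scores are transparent heuristics rather
than a trained classifier: evidence for *eye* is squared frontal loading
enrichment (Fp1/Fp2/F7/F8 share of absolute mixing weights relative to a
uniform topography) times the sub-4 Hz source-power fraction; *muscle*
analogously with temporal channels (T7/T8/FT9/FT10) and the above-20 Hz
fraction; normalized to probabilities against fixed brain/other evidence.
Components at or above the removal threshold are zeroed and the data
back-projected. The threshold is an explicit configuration value with the
conventional ladder 0.85 / 0.80 / 0.75 — noisier data may need a lower
rung, and since no objective criterion exists for that choice, the package
never auto-selects it.

## Spectral features

Stimuli are cut into 1-s windows every 0.5 s (50 % overlap, Hamming taper).
Each window's PSD is the tapered periodogram with Welch normalization
(divide by $f_s \sum w^2$, one-sided), averaged over windows, on the 1 Hz
grid 1–40 Hz (the 0 Hz bin lies in the high-pass region and is excluded).
Parseval holds within taper tolerance: a unit 10 Hz sine yields total
band-limited power ≈ 0.5 µV².

Band edges are configuration with conventional QEEG defaults — delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–40 Hz (half-open
intervals $(\ell, h]$, so the 1 Hz grid assigns bins 1–4, 5–8, 9–13, 14–30,
31–40). Two power conventions coexist deliberately: `band_abs` is the
*mean* PSD over a band's bins (the natural unit for absolute comparisons
across unequal band widths), while `band_rel` is the band's share of total
*summed* bin power, which guarantees $\sum_b R_b = 1$ exactly.

The brain rate is the relative-power-weighted mean of band centers,
$f_{BR} = \sum_b c_b R_b$ with $c_b = (\ell_b + h_b)/2$ — no closed formula
is fixed by convention, so both the centers and the definition are
config-overridable; with the default edges $R_\theta = R_\alpha = 0.5$
gives $f_{BR} = 8.25$ Hz.

Aggregation for the absolute analysis averages within participant first and
across participants second, so unequal stimulus counts cannot bias a
condition mean; the relative analysis deliberately keeps stimulus-level
rows unaveraged.

## Group statistics

**Permutation ANOVA.** Per (channel, frequency-bin) cell the observations
are within-participant PSD means per condition; the statistic is the
classical $F$; the p-value is $(1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$ under
uniform label permutation. Because total sum of squares is
permutation-invariant, permuted $F$s come from group sums alone, and the
whole grid shares each permutation draw, which is what makes 40,000
permutations over 1,280 cells affordable. Bonferroni uses the *global*
family (all tested cells) — the stricter of the two readings. Note the
arithmetic coupling: the minimum attainable p is $1/(n_\pi + 1)$, so
significance at $\alpha/m$ requires $n_\pi + 1 \ge m/\alpha$; the grid
default is $n_\pi = 39{,}999$. A within-participant permutation mode
(conditions shuffled inside each participant) is provided; full permutation
is the default.

**The cascade.** For each (site, measure, variable) cell — 31 channels × 5
band shares + brain rate × 5 grouping variables = 930 cells in the full
design — variance homogeneity (Levene, center = mean) and per-group
normality (Shapiro–Wilk) at 0.05 gate the test: Student t when both hold,
Welch t under heterogeneity, Mann–Whitney U when any group is non-normal
(or degenerate). P-values are pooled over all cells for Benjamini–Hochberg
(per-variable pooling is an option); the package reports the *realized*
adjusted alpha $p_{(i^*)}$ rather than hard-coding any particular value.
Cohen's d uses the pooled standard deviation and is reported signed
(tables conventionally print $|d|$).

The default observation unit is the stimulus-level row — the extensive
data set, which is knowingly pseudoreplicated (within-participant rows are
not independent, so stimulus-level p-values overstate evidence for
population-level claims). A `unit = "participant"` mode aggregates to
participant means first and is the defensible choice for inference; the
stimulus-level default mirrors the analysis this pipeline reproduces.

## The self-organizing map

Features per stimulus concatenate per-channel absolute band powers,
relative band powers and brain rate over the retained channels;
standardization centers/scales are stored in the model. The map is a 6 × 6
hexagonal grid trained for 10,000 iterations: draw a training row, find the
best-matching unit (BMU) by Euclidean distance, move every unit within the
current radius of the BMU toward the row (bubble neighborhood — all-or-none;
a Gaussian kernel is available). The learning rate decays linearly
0.05 → 0.01 and the radius from the 2/3 quantile of pairwise unit distances
to 0 — the "default radius" convention of the common SOM implementation
this mirrors. Training is unsupervised; units then take the majority label
of the training rows they capture, matching the clustering framing. A map
trained on well-separated clusters keeps interstitial "dead" units that no
training row maps to; held-out participants (whose baseline band factors
shift every feature slightly) frequently land on them, so `predict()`
classifies such rows by the nearest *labeled* unit in feature space — a
grid-distance fallback instead would let a dead unit inherit a label from
the wrong side of a cluster boundary.

The holdout is at participant level: whole participants go to one side, so
individual response patterns cannot leak across the split. The assignment
is found by a seeded shuffle plus an exact subset-sum search for the
achievable train-row count closest to `round(0.7 × rows)` — for 1,350 rows
the target 945/405 is hit exactly. Classification quality is reported as a
3 × 3 confusion matrix with per-class precision/recall/F1 and accuracy;
under the 120/15/15 design the majority-class rate is 0.8, which is the
reference point the zero-effect control must not exceed (a control that
beats it signals leakage, not skill).

## Problem sizes used by the test suite

The suite runs the full machinery at reduced, fixed scales chosen once as
adequate for their purpose: recovery of condition effects on the ANOVA grid
uses 10 participants × 30 stimuli × 4 s (40,000 permutations); cascade
recovery uses 12 participants with a 6/6 frequent/non-frequent split and a
+0.08 relative delta shift at three sites; SOM recovery uses 10
participants × 30 stimuli with band-power effects of 2–2.5× (or 0.4×)
against the generator's baseline noise; the type-I-error simulation uses
500 null replicates of 3 × 30 observations with 999 permutations. Design
counts (150 = 120 + 15 + 15, 930 tests, 945/405) are checked at the
original scale, which costs nothing.

## Numerical choices and degenerate inputs

* Zero total power in a spectrum: relative powers and brain rate are
  flagged `NA`, never 0/0.
* Zero within-group variance everywhere: observed $F$ is defined as 0 (no
  between-group signal) or ∞ (signal without noise, beating every finite
  permuted $F$); all-equal data give $p = 1$.
* A constant group is treated as non-normal (Shapiro–Wilk is undefined),
  routing to Mann–Whitney; a zero pooled sd makes Cohen's d `NA`.
* Shapiro–Wilk is limited to 5,000 observations; larger groups are tested
  on an evenly spaced deterministic subsample.
* Zero-variance SOM features are dropped with a warning; ties in BMU
  search and unit-label fallback break deterministically (first index,
  then codebook distance).
* Every stochastic step takes an explicit seed; per-participant generator
  substreams derive from (master seed, participant index) so designs are
  extensible without perturbing existing data.

## Known limitations

The generator's independence across channels means topographic statistics
(e.g. ICA unmixing) face an easier problem than real EEG; the heuristic
component scorer is validated against generator artifacts, not against
labeled human data; stimulus-level cascade inference is pseudoreplicated by
design (see above); and the pipeline makes no attempt at cluster-based
permutation correction or connectivity measures. The package's interface
is its functions and this vignette — `run_pipeline()` orchestrates the
stages from one `pipeline_config()`, and `scripts/acceptance.R` re-derives
the headline numbers from scratch; no separate shell tool is provided.
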