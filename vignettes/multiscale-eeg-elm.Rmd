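---
title: "Multiscale singular-value features and ELM classification of multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale singular-value features and ELM classification of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsvd)
```

## The problem

Active noise control (ANC) headphones generate anti-phase sound to cancel
ambient noise. A natural neurophysiological question is whether the brain's
electrical activity distinguishes listening *through* ANC from ordinary
listening — e.g. silence, broadband noise, music, noise heard through an ANC
headset, and music played through an ANC headset over background noise. If a
classifier can separate these five listening conditions from multichannel
EEG alone, the conditions evoke measurably different cortical activity.

`eegsvd` implements the complete analysis pipeline for this question:

1. **Band-limiting** each 19-channel, 256 Hz recording to 0.5–75 Hz.
2. **Framing** into non-overlapping 512-sample (2 s) frames.
3. **Multiscale decomposition** of every channel with a five-level `db4`
   discrete wavelet transform (DWT), and reconstruction of the per-scale
   *sub-band signals*, stacked channel-wise into six 512 × 19 *sub-band
   matrices* `A5, D5, D4, D3, D2, D1`.
4. **Eigenfeatures**: the first eight singular values of the `A5`
   (delta), `D5` (theta), `D4` (alpha) and `D3` (beta) matrices,
   concatenated into a 32-dimensional feature vector per frame.
5. **Classification** with an extreme learning machine (ELM) under
   stratified 5-fold cross-validation, reporting per-class sensitivity and
   overall accuracy, plus one-way ANOVA screening of each feature.

Because no public recordings of this experiment exist, the package ships a
first-class synthetic generator that emulates the recording conditions, so
every stage is testable end to end.

## The model

### Dyadic scales and clinical rhythms

At `fs = 256` Hz a five-level dyadic decomposition produces nominal bands
0–4 (`A5`), 4–8 (`D5`), 8–16 (`D4`), 16–32 (`D3`), 32–64 (`D2`) and
64–128 Hz (`D1`). The first four are taken as carriers of the clinical
delta, theta, alpha and beta rhythms. The dyadic alpha (8–16 Hz) and beta
(16–32 Hz) scales are wider than the clinical 8–14 / 14–30 Hz definitions;
the dyadic mapping is used for feature extraction because it is what the
filter bank computes, while the generator synthesises rhythms at the
clinical ranges — the mismatch is deliberate and mirrors how such pipelines
behave on real data.

```{r bands}
sapply(subband_names(5), band_range, fs = 256)
```

### Why singular values

For a frame `X` (time × channels), each sub-band matrix `X_b` is the
band's additive contribution per channel (the six matrices sum to `X`
exactly). Its singular value decomposition `X_b = U Λ V'` concentrates the
band's spatio-temporal energy: the squared singular values sum to
`‖X_b‖_F²`, and their decay describes how many spatial modes the rhythm
occupies. The leading eight values per band are therefore a compact,
montage-aware summary of band power and spatial coherence. They are kept
raw (not normalised by frame energy): absolute band amplitude is itself
discriminative between listening conditions.

### The classifier

The ELM is a single-hidden-layer network whose hidden weights and biases
are drawn uniformly on [−1, 1] once and never trained; only the output
layer is solved, as the ridge problem

    B = (H'H + I/C)⁻¹ H'Y

with `H` the activated hidden matrix and `Y` the 0/1 one-hot targets
(class *i* coded with a single 1 at output neuron `q − i + 1`, i.e.
`00001`, `00010`, …, `10000`). Predicted labels take the maximal output
neuron, ties broken toward the lowest class index. Three activations are
supported: `sigmoid`, `sine`, and the radial basis `radbas(u) = exp(−u²)`.

### Evaluation

The per-class sensitivity is `SE_i = a_ii / Σ_j a_ij × 100` from the
pooled confusion matrix, and the overall accuracy is the **macro average**
`OA = mean(SE_i)` — not the pooled fraction of correct predictions; with
balanced classes the two coincide, otherwise they deliberately differ.
Folds are stratified by class and seeded; per-fold confusion matrices are
summed before computing `SE`/`OA`, matching the convention of reporting one
sensitivity table per configuration.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fs` | 256 Hz | sampling rate |
| `duration_s` | 420 s | session length per condition (7 min → 210 frames) |
| `hp_hz`, `lp_hz` | 0.5, 75 Hz | Butterworth band-limiting cut-offs (order 4, zero-phase) |
| `frame_len` | 512 | samples per frame; must be divisible by `2^levels` |
| `levels`, `wavelet` | 5, `db4` | decomposition depth and mother wavelet |
| `k` | 8 | singular values kept per band (≤ 19 channels) |
| `h` | 100 | hidden neurons; ~3× the feature count is ample for 32 features |
| `C` | 1 | ridge constant; larger values regularise less |
| `activation` | `radbas` | hidden activation |
| `folds` | 5 | cross-validation folds |

`h` and `C` are conventional ELM defaults for this feature dimensionality,
exposed for sensitivity studies; results in the package's tests are not
finely dependent on either. Feature min–max scaling to [0, 1] is fitted on
the training folds only, which keeps the hidden layer out of saturation for
the sigmoid and radbas activations.

## The synthetic generator

`synth_recording()` builds each rhythm band as white noise passed through a
4th-order Butterworth band-pass (delta 0.5–4, theta 4–8, alpha 8–14, beta
14–30 Hz), scaled to a per-condition RMS amplitude. Realism knobs:

* **Spatial correlation** — each band mixes one source shared by all
  channels with independent per-channel residuals
  (`spatial_mixing_strength` ∈ [0, 1]). This matters because singular-value
  features are rank-sensitive: fully independent channels give a flat
  spectrum, a single shared source a rank-1 one. The default 0.5 sits
  between the extremes.
* **Amplitude jitter** — a slow (< 0.2 Hz) multiplicative envelope with
  relative depth `jitter` makes band power vary between frames, giving each
  class a within-class dispersion.
* **Nuisance components** — broadband sensor noise (2 µV RMS), sub-0.5 Hz
  baseline drift (5 µV RMS) and >75 Hz artifact (1 µV RMS), all removed by
  the band-limiting stage; they exist to exercise the filters.

The default condition profiles encode only the qualitative structure the
five conditions are expected to show: the noise condition has the highest
band amplitudes, the two ANC conditions the lowest, and ANC with music the
smallest jitter (steady, focused listening). The absolute microvolt values
are free parameters chosen once at plausible resting-EEG magnitudes
(delta ≈ 16–24, theta ≈ 8–13, alpha ≈ 9–16, beta ≈ 4.5–8 µV RMS); no
quantitative spectra per condition are available to calibrate against, so
no numeric claim about real recordings is attached to them.
`synth_profiles(separation = s)` scales the between-class gaps around the
grand mean, which the tests use to verify that cross-validated accuracy
rises monotonically with class separation.

What the generator does **not** emulate: EEG morphology (spindles, eye
blinks, muscle artifacts), inter-subject variability (a single statistical
"subject" is modelled, since no per-subject results exist to compare
against), non-stationarity beyond slow amplitude modulation, and volume
conduction geometry. Passing tests therefore demonstrate that the pipeline
recovers class structure *of this statistical form*, not that it would
reach any particular accuracy on clinical recordings.

Note one subtlety: with `separation = 0` all class amplitudes coincide but
the per-class jitters still differ, so classification accuracy stays
somewhat above the 20% chance level — dispersion itself is a legitimate
class cue. Shuffling labels, by contrast, drives accuracy to chance.

## Numerical choices

* **Zero-phase filtering.** Band-limiting runs the Butterworth filters
  forward and backward, so no group delay is introduced between channels
  (the sub-band matrices assume synchronous channels). The recursion is
  performed as a cascade of second-order sections: a direct-form 0.5 Hz
  high-pass at `fs = 256` has poles close enough to the unit circle to
  lose ~7 digits in double precision, while the cascade keeps filtering
  linear to ~1e−13. Edges use odd reflection plus steady-state initial
  conditions (a constant input yields its steady-state response from
  sample one); residual edge transients decay within ~2 s of the ends.
* **Periodized DWT.** Boundary handling is periodization, which keeps the
  transform orthonormal, makes coefficient counts halve exactly
  (512 → 256/128/64/32/16 + 16) and gives perfect reconstruction to
  ~1e−15. The filter taps are the standard `db4` orthonormal set; a
  single analysis step is pinned to an independent reference
  implementation in the tests.
* **Ridge solve.** The output weights use the primal form
  `(H'H + I/C)⁻¹H'Y` (`h ≤ n` expected); tests cross-check against an
  augmented-QR least-squares route. Interpolation at `h ≥ n`, `C = 1e8`
  is verified with the radbas activation, which conditions `H` best.
* **Ties and degenerate inputs.** Prediction ties break to the lowest
  class index; sensitivities of empty confusion rows raise an error rather
  than silently reporting zero; ANOVA refuses all-constant groups.
* **Determinism.** Every stochastic stage takes an explicit seed, derived
  from one global seed by a fixed affine map, and restores the caller's
  RNG state. Text artifacts are written at 9 significant digits so equal
  configurations give byte-identical files.

## Design decisions

* Frames are non-overlapping; a 7-minute session yields exactly
  `floor(107520 / 512) = 210` frames, and an incomplete tail is discarded.
* `D2`/`D1` sub-band matrices are computed (they complete the perfect
  reconstruction identity) but contribute no features — only the four
  rhythm-bearing scales do.
* ANOVA p-values are reported per feature without multiple-testing
  correction, matching the screening use (a feature enters the classifier
  regardless; the screen is descriptive).
* The two-class contrast (music versus ANC with noise and music) reuses
  the same machinery with two output neurons; `OA` is then the mean of two
  sensitivities.
* Whether frames should be pooled across subjects before cross-validation
  is moot here (one synthetic subject); the pipeline pools, and the run
  manifest records the configuration.

## Problem sizes

The test-suite defaults are deliberately modest: sessions of 4–32 s,
3–15 frames per class for pipeline checks, and 100 frames per class for the
class-recovery and chance-level checks. `scripts/acceptance.R` uses full
7-minute sessions and 100 frames per class. These sizes give stable
statistics (binomial standard error on a 500-frame OA is ~2 percentage
points) while keeping a complete run in minutes on one core.

## Known limitations

* Only the `db4` wavelet is implemented; the mother wavelet is part of the
  method, not a free parameter here.
* The EDF writer/reader supports the minimal subset used by this package
  (common sampling rate, 1-second records, 16-bit symmetric quantisation).
* Periodized framing requires `frame_len` divisible by `2^levels`.
* Accuracy figures on synthetic data characterise the pipeline, not human
  EEG; the generator's profiles are stand-ins, and none of its outputs
  should be read as a claim about real listening conditions.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(duration_s = 60, n_per_class = 20, seed = 7)
cv <- run_pipeline(cfg, out_dir = tempfile("eegsvd-run-"))
glance(cv)
tidy(cv)
autoplot(cv)
```
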