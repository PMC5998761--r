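# eegsvd

Multiscale singular-value features and extreme-learning-machine (ELM)
classification of multichannel EEG recorded under different auditory
listening conditions — silence, broadband noise, music, and active noise
control (ANC) with and without music.

The package is for signal-processing and neurophysiology researchers who
want a fully reproducible, tested implementation of this pipeline:

1. **Band-limit** each 19-channel, 256 Hz recording to 0.5–75 Hz
   (zero-phase 4th-order Butterworth).
2. **Segment** into non-overlapping 512-sample frames (512 × 19 matrices).
3. **Decompose** every channel with a five-level `db4` discrete wavelet
   transform and stack the per-scale sub-band signals into six sub-band
   matrices `X_A5, X_D5, …, X_D1` (each 512 × 19, summing exactly to the
   frame).
4. **Extract features**: the first eight singular values of
   `X_A5` (delta), `X_D5` (theta), `X_D4` (alpha) and `X_D3` (beta) —
   a 32-dimensional vector per frame. For `X = U Λ Vᵀ`, the singular
   values `σ₁ ≥ σ₂ ≥ …` satisfy `Σσᵢ² = ‖X‖²_F`, so each block is an
   energy-preserving summary of one rhythm's strength and spatial
   coherence.
5. **Classify** with an ELM — random hidden layer, output weights solved
   as the ridge problem `B = (HᵀH + I/C)⁻¹HᵀY` — under stratified 5-fold
   cross-validation, reporting per-class sensitivity
   `SE_i = a_ii / Σ_j a_ij × 100` and overall accuracy `OA = mean(SE_i)`,
   plus one-way ANOVA screening of every feature.

No public recordings of this experiment exist, so the package includes a
seeded synthetic generator (`synth_recording()`, `synth_frames()`) that
emulates the recording conditions — condition-dependent delta/theta/alpha/
beta band-power profiles with controllable spatial correlation, plus
baseline drift and high-frequency artifact for the filters to remove.
All results below are computed on synthetic data and characterise the
pipeline, not human EEG.

## A worked example

```r
library(eegsvd)

cfg      <- synth_config(duration_s = 60)            # 19 ch @ 256 Hz, 1 min
frames   <- synth_frames(cfg, n_per_class = 20, seed = 7)
features <- eeg_features(frames)                     # 100 x 34 tibble

cv <- elm_cross_validate(features, band = "total", activation = "radbas",
                         seed = 7)
cv
#> <elm_cv> 5-fold CV, band = total, activation = radbas, h = 100, C = 1
#> overall accuracy: 72.00%
#>          silent           noise           music       anc_noise anc_noise_music
#>              75              95              50              70              70
```

The noise condition is easiest to recognise (its band amplitudes are the
highest of the five profiles) and music the hardest (its profile sits close
to silence); the overall accuracy, 72%, is the macro-average of the five
sensitivities. Feature screening shows strong class dependence throughout:

```r
head(dplyr::arrange(anova_screen(features), p.value), 3)
#> # A tibble: 3 × 4
#>   feature band  statistic  p.value
#> 1 beta_5  beta       138. 1.23e-38
#> 2 beta_6  beta       137. 1.59e-38
#> 3 alpha_8 alpha      136. 1.85e-38
```

Single frames expose the lower-level interfaces:

```r
fv <- frame_features(frames$frame[[1]])   # 32 named singular values
round(band_subset(fv, "alpha"), 3)
#> alpha_1 alpha_2 alpha_3 alpha_4 alpha_5 alpha_6 alpha_7 alpha_8
#> 993.772 480.455 310.518 274.460 238.692 228.808 216.283 182.996
```

`run_pipeline(run_config(...), out_dir)` chains everything and writes
`features.csv`, `results.csv` (sensitivities and OA for every band subset ×
activation) and `manifest.json`; two runs with the same configuration give
byte-identical CSV artifacts. `tidy()`, `glance()` and `autoplot()` methods
cover fitted models and cross-validation results, and recordings round-trip
through CSV and EDF (`write_eeg_csv()`, `write_eeg_edf()`, …).

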