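---
title: "EEG biomarkers of motor vigor: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG biomarkers of motor vigor: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A squeeze-bulb task yields, per trial, a pressure trace and a multichannel
EEG segment. Motor vigor (MV) is defined behaviorally as the inverse of the
time from the Go cue to peak force, `MV = 1/(t3 - t1)` in ms⁻¹; the argmax
of the pressure trace over post-cue samples defines the peak, with ties
broken toward the earliest sample (first attainment of maximum force), and
no smoothing before the argmax by default. With peak times of 300–1200 ms,
MV values sit around 1.4e-3 ms⁻¹.

The scientific question is how much of the trial-to-trial variability of MV
is linearly decodable from EEG features computed in the second before peak
force, and how that decodability differs by disease group, stimulation
condition, and EEG band. The decoder is deliberately simple — L1-penalized
linear regression — so that the selected coefficients remain interpretable
as band/channel contributions.

## Preprocessing chain

The chain is: band-pass filter → wavelet artifact suppression → peak-locked
epoching → decimation augmentation → outlier clipping → (feature
extraction) → within-subject z-scoring. Re-running the chain on identical
input is bit-identical.

* **Band-pass 0.5–45 Hz.** Windowed-sinc (Hamming) FIR applied
  forward-backward (`signal::filtfilt`), so the effective response is
  zero-phase with squared magnitude. At the default order of 3000 the
  realized attenuation is below −40 dB at 0.1 Hz and at 55 Hz with a flat
  passband (±1% at 10 Hz). A filter of order L needs a signal longer than
  3L samples; per-trial segments of a few seconds therefore use a
  configurable shorter filter (order 750 in `preprocess_cohort()`), whose
  low-edge rolloff is gentler. The full-order default is intended for
  continuous recordings.
* **Wavelet artifact suppression.** A stationary (maximal-overlap,
  circular-boundary) wavelet transform with the sym4 filter pair, depth 5.
  At each level, detail coefficients are *clamped* at the universal
  threshold `sigma_j * sqrt(2 log n)`, with `sigma_j` the MAD estimate
  from that level's own coefficients. The level-wise clamping direction is
  deliberate: classical soft-shrinkage denoising subtracts the threshold
  from large coefficients and therefore barely touches a high-amplitude
  transient (a 20×RMS spike would retain ~95% of its amplitude); artifact
  suppression requires the dual operation — outliers relative to their
  level's typical scale are pulled down to it, while sustained band-limited
  rhythms, which *set* their level's scale, pass essentially unchanged
  (spikes attenuated ≥75%, clean sinusoid correlation >0.99 in the test
  fixtures). The transform and its exact inverse are implemented in the
  package (round-trip error below 1e-10); the depth is capped at
  `floor(log2(n/8))` for short inputs, and the circular transform accepts
  any length.
* **Epoching.** The analysis epoch is the window `(t_peak - 1000 ms,
  t_peak]` — half-open so the peak sample is included exactly once. Trials
  without 1000 ms of pre-peak signal are rejected and logged, never
  silently dropped.
* **Augmentation.** Each 1000-sample epoch is split into its even- and
  odd-indexed sample streams: two 500-sample epochs at 500 Hz sharing the
  trial's MV label. No anti-alias filtering is added because the content is
  already limited to 45 Hz, far below the new 250 Hz Nyquist; interleaving
  the two streams reconstructs the original exactly. Downstream, the two
  siblings always travel together through train/test splits.
* **Clipping.** Per channel per epoch, samples beyond mean ± 3 SD (computed
  before clipping) are set to the bound. Per-channel statistics were chosen
  (over per-epoch-global) for robustness to inter-channel scale
  differences.
* **Z-scoring.** Features and MV are standardized within subject, pooling
  that subject's trials across conditions, using the population-SD
  (divide-by-n) convention. Pooling across conditions removes subject
  offsets while preserving condition contrasts. Standardization happens
  before the train/test split; this mirrors the narrative order of the
  analysis being reproduced, and the small per-subject leakage it can
  introduce is shared by all models being compared.

## The 53-feature bank

Per channel, per 500-sample 500 Hz epoch:

| family | count | definition |
|---|---|---|
| `rel_power` | 6 | band power ÷ total power over 0.5–45 Hz (trapezoidal integration of the Welch PSD; the six shares sum to 1 by construction) |
| `harm_fc`, `harm_bw`, `harm_sfc` | 18 | per band: spectral centroid `fc = Σ f·S/ΣS`, spread `fσ = sqrt(Σ(f-fc)²S/ΣS)`, and the density at the grid frequency nearest `fc` |
| `bisp_amp`, `bisp_phase` | 28 | mean bispectral magnitude, and argument of the region-mean complex bispectrum, over 14 canonical band-pair regions |
| `spec_entropy` | 1 | Shannon entropy of the six relative band powers, normalized by log 6 |

Total: 53 per channel; 1431 for the 27-channel montage. The composition is
configuration-driven and validated to total 53.

The PSD is a Welch estimate: 256-sample Hann segments, 50% overlap, FFT
length 512, density normalized so the integrated PSD equals the
time-domain variance (Parseval, within 5–10% in tests). The bispectrum is
the direct segment-averaged estimator (128-sample Hann segments, 50%
overlap): `B(f1,f2) = mean_k X_k(f1) X_k(f2) conj(X_k(f1+f2))` on the
principal domain `0 ≤ f2 ≤ f1, f1+f2 ≤ fs/2`. It equals a brute-force
triple-product computation to 1e-10 relative error, shows a ≥10× diagonal
peak with biphase ≈ 0 for a quadratically phase-coupled cosine triple, and
decays to the noise floor for independent-phase tones as segments
accumulate. Scale behavior is the expected homogeneity: relative powers,
centroids, spreads, entropy and biphase are scale-invariant; `S(fc)`
scales as c², bispectral amplitude as c³.

The 14 band pairs are the first 14 ordered pairs (i ≤ j in band order)
whose rectangular bifrequency region intersects the principal domain:
δδ, δθ, δαl, δαh, δβ, δγ, θθ, θαl, θαh, θβ, θγ, αlαl, αlαh, αlβ. For
band-restricted models a pair feature belongs to both member bands, and
spectral entropy belongs only to the broadband model — any band's model
should see every feature carrying that band's information.

Harmonic parameters interpret "per-band spectral summary" as the moment
triple (centroid, spread, density-at-centroid); this is the standard
reading but the exact original formulas are not published, so the bank is
swappable by configuration.

## The bootstrapped LASSO

Each of 40 iterations draws a random 80/20 split at the *trial* level
(augmented siblings co-travel — splitting them would leak nearly duplicate
epochs across the boundary). The penalty is chosen per iteration by
10-fold cross-validation on the training 80% only, minimizing CV MSE over
glmnet's 100-point logarithmic path. Performance is the Pearson
correlation between held-out predictions and observations; correlations
are averaged on the Fisher-z scale. Resampling is pooled across subjects
within each (group × stimulus) cell, and cells are fit separately per
(group × stimulus × band-model), giving the 2 × 3 × 7 design.

Degenerate cases are handled explicitly: a split whose held-out *observed*
MV has zero variance is redrawn with a new seed (logged); a fitted model
with no selected features produces constant predictions, and its
performance is recorded as 0 with a `degenerate` flag — a model with no
features carries no predictive association, and this convention keeps null
calibration honest (the alternative, dropping such runs, would bias null
performance upward).

Coefficient aggregation reports, per feature and per (channel, band): the
mean coefficient over all runs, the mean over non-zero occurrences only,
and the selection frequency. One-sample t-tests on aggregated coefficients
and the mixed ANOVAs below complete the inferential layer.

## Statistical layer

`mixed_anova()` implements the classical univariate mixed ANOVA for
balanced designs via the standard error strata (unit, unit×within), with
partial η² = SS_effect/(SS_effect + SS_error) from each effect's own
stratum. For within effects with ≥3 levels the Greenhouse–Geisser ε and
Mauchly's test are computed from the pooled within-group covariance of
orthonormal effect contrasts; the GG-corrected p is reported alongside the
uncorrected one (correction recommended when Mauchly's p < 0.05). All
statistics reduce to textbook closed forms and are verified against an
independently written brute-force sums-of-squares oracle to 1e-10 on small
inputs; null simulations confirm uniform p-values and a 5% one-sample-t
type-I rate.

The unit of analysis for the performance ANOVA is the bootstrap run
(group × iteration), whose z-transformed performance is crossed with
stimulus and band. Subject-level MV means are the unit for the behavioral
2 × 3 ANOVA.

## The synthetic cohort generator

The generator reproduces the study conditions: 20 HC + 18 PD subjects,
three condition blocks (sham, GVS1, GVS2) of 10 trials, 27 channels at
1 kHz, and per-trial timing of a 1500 ± 500 ms jittered fixation, 500 ms
Go screen and 1000 ms blank — so every Go onset lies in [1000, 2000] ms
and each trial's continuous segment covers the full trial.

* **Behavior.** Time-to-peak is lognormal with mean 700 ms and SD 120 ms,
  truncated to [300, 1200] ms, which puts the reference-condition mean MV
  near 14e-4 ms⁻¹; GVS conditions multiply MV by 15.5/14 and 15.4/14 —
  the observed condition-mean ratios. Pressure traces rise after a
  ~200 ms reaction delay to a designed peak (two-sided exponential, so the
  peak survives additive noise at the sample level) and decay afterwards.
* **EEG.** Each channel is unit-variance 1/f Gaussian noise (5 µV SD,
  spectral shaping by FFT) plus one band-centered sinusoid per band
  (baseline amplitudes 4, 3, 5, 3, 2.5, 1.5 µV for δ…γ — a plausible
  resting composition; no inter-channel correlation, keeping LASSO
  selection non-trivial without a source model).
* **Planted coupling.** For a target (channel, band, family) with weight w
  and coupling noise σ, the band oscillation power is multiplied by
  `m = 1 + 0.35 (w·z + σ·ε)` with `z` the standardized MV and ε fresh
  standard normal noise (the 0.35 scale keeps the truncation of m at 0.05
  rare). Power-type features are linear in m, so with `w = sqrt(R²)`,
  `σ = sqrt(1-R²)` the planted feature–MV coupling has population R² ≈ R²;
  the coupled band uses a dedicated 12 µV baseline amplitude so that the
  planted relation dominates the in-band background. Measured calibration
  at 400–500 trials: requested 0.25/0.50/0.75 → recovered ≈
  0.25/0.49/0.72 on the power-at-centroid target. Relative-power targets
  recover less (≈0.50 for a requested 0.75) because the normalizing
  denominator fluctuates with the epoch-to-epoch composition of the 1/f
  background — an inherent property of relative measures, so requested-R²
  calibration is stated for power-type targets. Bispectral targets drive
  the coupled fraction of a three-cosine quadratic-phase-coupled triple at
  the band-pair centers.
* **What it does not emulate.** Volume conduction and inter-channel
  correlation, non-stationarity within a trial, ocular/muscle artifact
  morphology, stimulation artifacts, or any vestibular physiology. Passing
  tests on this cohort demonstrate that the pipeline recovers planted
  structure at realistic SNR and scale — not that real EEG carries such
  structure.

## Calibration and problem sizes used in the test suites

Planted-signal recovery (mean held-out r within ±0.1 of √R² for R² in
{0.25, 0.5, 0.75}) is measured at n = 400 epochs with 5 planted features
and 40 bootstrap runs on a single-channel (53-column) bank: at that n the
LASSO is close to the oracle and the measurement reflects the planted
calibration rather than high-dimensional estimation error. Selection
fidelity is measured on the full 1431-column bank (5 planted features,
standardized effects ≈ 0.32): planted selection frequency reaches 1.0 and
the null median 0; at that width the held-out correlation itself sits
~0.06 below √R² at R² = 0.5 and further below at R² = 0.25, the expected
price of 1431 candidate predictors at modest SNR. Sign recovery uses 20
replicates of 8 runs each. Null calibration uses 20 replicates × 40 runs
on a 318-column bank (n = 200), 1000 one-sample-t replicates, and 500
null mixed-ANOVA replicates; the pipeline smoke test runs a 4-subject,
3-channel cohort through all 42 design cells.

## Known limitations

* The exact feature formulas and wavelet settings of the original analysis
  are unpublished; the defaults here are standard readings, and all are
  configurable.
* Band containment of narrowband activity is resolution-limited: with
  256-sample Hann segments at 500 Hz, a mid-band tone leaks ~10% of its
  power into neighboring bands; containment to within 5% needs 512-sample
  segments.
* The per-trial FIR filter cannot achieve the full low-edge sharpness of
  the long-recording default (see above).
* `performance_r = 0` for empty models is a convention; cells whose runs
  are predominantly degenerate should be interpreted via selection
  frequencies, not mean r alone.
* The mixed ANOVA assumes balanced designs and errors out otherwise; it
  does not fit unbalanced or missing-cell data.
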