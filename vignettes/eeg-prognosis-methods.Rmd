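---
title: "Methods: pre/post resting-EEG biomarkers and treatment-response prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre/post resting-EEG biomarkers and treatment-response prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegprognosr)
```

## The analysis problem

`eegprognosr` implements a complete analysis pipeline for small paired
(pre/post treatment) resting-state EEG studies on the 16-lead 10-20 montage
(Fp1/Fp2, F3/F4, C3/C4, P3/P4, O1/O2, F7/F8, T3/T4, T5/T6). The motivating
setting is one week of low-frequency TMS for chronic insomnia, with sleep
quality quantified by two questionnaires: the PSQI (total 0-21) and the ISI
(total 0-28), both administered before and after treatment. Throughout the
package the change convention is **after minus before**, so clinical
improvement is a *negative* score change. Correlations are invariant to a
consistent sign convention; it is stated once here and used everywhere.

The pipeline answers three questions:

1. Which EEG features changed between the pre- and post-treatment
   recordings (paired t-tests over the indicator grid)?
2. Which feature changes track the clinical score changes (Pearson
   correlations against the PSQI/ISI changes)?
3. Can the selected feature changes *predict* a subject's score change
   (leave-one-out support-vector regression, validated by a permutation
   test)?

## Feature grid

Every recording is reduced to a grid of 8 features x 5 bands x 16
channels = 640 values. An "indicator" is a (feature, band) pair — 40
indicators, each evaluated at 16 channels. The features:

* **ApEn** — approximate entropy (Pincus): `Phi_m - Phi_(m+1)` with
  self-matches included, Chebyshev distance, natural log.
* **SampEn** — sample entropy (Richman-Moorman): `-log(A/B)` with
  self-matches excluded. When no template pairs match at length `m`,
  SampEn is undefined and the cell is reported missing, then excluded
  pairwise downstream — never silently imputed.
* **PE** — permutation entropy (Bandt-Pompe): Shannon entropy of ordinal
  patterns, normalized by `log(order!)` to lie in [0, 1]; ties broken by
  order of appearance.
* **PSD** — band power: the Welch spectral density (Hann taper, 2 s
  segments, 50% overlap, per-segment mean removal) integrated over the
  band. One number per band and channel, which is why the indicator grid
  treats "PSD" as a single feature.
* **median, mean, skewness, kurtosis** — distribution moments of the
  band-limited signal. Skewness is the population Fisher-Pearson `g1`;
  kurtosis is *excess* kurtosis `g2` (normal gives 0). Band-passed signals
  are zero-mean by construction, so the mean and median features are
  nearly degenerate; they are kept for completeness of the grid but carry
  essentially no information.

### Parameter choices

The entropy parameters are the conventional defaults for short
physiological series, exposed in `feature_params()`:

| parameter | default | why |
|---|---|---|
| embedding dimension `m` | 2 | standard for biomedical series |
| tolerance `r` | 0.2 x SD | recomputed per band-limited channel signal, because band amplitudes differ by orders of magnitude |
| PE order / delay | 3 / 1 | 6 ordinal patterns; robust at a few hundred samples |
| Welch window / overlap | 2 s / 0.5 | 0.5 Hz resolution, enough for a 1 Hz band edge |

ApEn/SampEn template matching is quadratic in series length, and at
`m = 2` the estimates saturate after a few thousand points, so the
entropies are evaluated on at most `entropy_max_samples` (default 2500)
leading samples of the clean band-limited signal. All other features use
the full signal.

Features are computed on the **concatenated artifact-free signal**, not
averaged over 1-s epochs: a 1-s delta-band epoch holds only 1-4 cycles,
which makes per-epoch entropy and spectral estimates unstable. A
per-epoch-mean mode (`per_epoch = TRUE`) is available for sensitivity
analysis.

## Preprocessing

* Broadband filter: a nominal "0-45 Hz" setting is implemented as a
  0.5-45 Hz zero-phase (forward-backward) 4th-order Butterworth; a true DC
  passband keeps slow drift that corrupts the entropy and moment features.
  The low cut is configurable.
* Epoching: non-overlapping 1-s windows; a trailing remainder is dropped.
* Artifact screening: epochs whose peak absolute amplitude exceeds
  100 uV on any channel are flagged and excluded. This amplitude screen is
  the package's substitute for manual ICA-based cleaning, which needs an
  operator in the loop; its threshold is a parameter.
* Band decomposition: delta [1, 4), theta [4, 8), alpha [8, 13),
  beta [13, 30), gamma [30, 45] Hz. Shared edges belong to the upper band
  (half-open convention), so nothing is double-counted; gamma closes at
  the 45 Hz global low-pass edge. Band filtering operates on the
  concatenated retained signal and is re-segmented afterwards, again to
  avoid slow-band edge effects in 1-s windows.

The tests verify passband fidelity (±5% on an in-band tone), stopband
rejection, two-tone separation with < 10% cross-talk, band-energy
additivity within 15%, and that epoch concatenation is exact.

## Group statistics

`ttest_all_indicators()` runs one classical paired t-test per grid cell
(two-tailed, n-1 df). `correlate_with_outcome()` computes Pearson r and a
two-tailed p per cell against the chosen scale's change.
`select_significant()` filters at `alpha = 0.05` with **no multiple-testing
correction by default** — the convention of the exploratory pre/post
literature this pipeline mirrors. That choice inflates the family-wise
error over a 640-cell grid and is deliberately exposed: Benjamini-Hochberg
(or any `p.adjust` method) is one flag away, and the nested prognosis mode
(below) quantifies how much the uncorrected selection flatters the model.

`responder_rate()` implements the literal fractional-reduction rule: a
subject responds when `(before - after) / before >= 0.25`. On the packaged
study table this gives 7/15 (PSQI) and 9/15 (ISI).

## Prognostic model

For one scale, the selected indicators' changes form the predictor matrix
`X` (subjects x indicators) and the scale change is the outcome `y`.

* **Model**: epsilon-SVR, RBF kernel, `C = 1`, `epsilon = 0.1`,
  `gamma = 1/(d x mean feature variance)` (i.e. `1/d` after
  standardization). These are the common defaults; no hyperparameter
  search is performed, because with n ~ 15 subjects any tuned optimum
  would be noise. A linear kernel is available.
* **Evaluation**: leave-one-out. Standardization statistics and
  constant-column screening are computed on each training fold only; the
  held-out subject never influences its own scaler (unit-tested).
* **Significance**: the observed statistic is Pearson r between the LOO
  predictions and the true changes. The null is built by permuting the
  rows of `X` (outcomes fixed — equivalent, under exchangeability, to
  permuting `y`) and recomputing the full LOO correlation; the default
  null size is 5000 draws. The p-value is one-sided toward positive r — a
  useful prognostic model must predict positively — with the add-one
  correction `p = (#{null >= observed} + 1)/(N + 1)`, so `p` is never
  exactly 0.

Two selection modes exist. The default `"full"` mode selects indicators
once on the full sample before cross-validation, mirroring common practice;
it is optimistic because the held-out subject contributes to the
selection. The `"nested"` mode repeats selection inside every LOO fold and
every permutation and is leakage-free; under null data its rejection rate
stays near the nominal level (tested). The permutation test partially
protects the full mode as well — the selection optimism inflates the
observed r and the null r alike only when selection is also permuted,
which is exactly what nested mode does, so nested is the defensible choice
for any confirmatory claim.

## Synthetic cohorts

Because raw clinical EEG cannot ship with the package, a seeded generator
(`synthetic_config()`, `generate_cohort()`) produces cohorts with known
planted structure; it exists so that every downstream stage has a ground
truth, and it is itself part of the tested surface.

Each channel is a sum over the five bands of a fixed-amplitude sinusoid —
carrier frequency drawn uniformly inside the band, per channel, fixed per
subject across sessions so pre and post differ only by the planted effect
and the noise realization — over 1/f^alpha Gaussian background noise
(alpha = 1, spectral shaping in the Fourier domain). Defaults: 250 Hz,
300 s (a 5-minute resting recording), band amplitudes
delta 20 / theta 10 / alpha 20 / beta 5 / gamma 2 uV, noise SD 10 uV — a
conventional awake eyes-closed profile with a dominant alpha rhythm. The
source study does not characterize its amplitude or spectral
distributions, so these are conventional values, not fitted ones.

Per subject, an integer score change is drawn from a normal distribution
(default mean -4.4, SD 4 — the magnitude of the packaged study's observed
one-week changes, whose PSQI and ISI means are -3.3 and -5.5), clipped to
the instrument range. The post-session amplitude of `effect_band` at
`effect_channel` is `pre x (1 + effect_size x change)` for the instrument
named by `effect_scale`; the configuration errors out rather than allow a
nonpositive amplitude. With `effect_size = 0` the cohort is an exact null.
Because the scale table carries two instruments but the planted effect is
driven by one score change, the generator draws each instrument's change
independently and ties the amplitude link to `effect_scale` (default ISI).

What the generator does **not** emulate: eye-blink/EMG artifact
morphology, sleep microstructure, inter-channel volume-conduction
correlation, or stimulation physics. Passing tests on synthetic cohorts
therefore demonstrate the statistical machinery — calibration, leakage
freedom, power against a planted effect — not clinical validity on real
recordings.

## Numerical and degenerate-input choices

* Zero-variance series: the entropy tolerance `0.2 x SD` would be 0, so the
  cell is reported missing rather than computed; paired t-tests and
  correlations on zero-variance vectors are flagged untestable, not run.
* SampEn with matches at `m` but none at `m + 1` returns `Inf`, which the
  feature table also treats as missing.
* ApEn of a strictly periodic series can be marginally negative — a known
  artifact of the self-match convention; values are reported as computed
  so they remain exactly comparable to the brute-force definition.
* Grid cells with fewer than 3 complete pairs are flagged untestable and
  their `n_effective` recorded (pairwise deletion).
* EDF output quantizes to 16 bits with per-channel physical scaling; the
  round-trip error is bounded by one digitization step.

## Verification strategy and problem sizes

The test suite checks every stage against an independent oracle: ApEn and
SampEn against naive double-loop implementations of the definitions
(exact equality on 100 random short series), PE against hand enumeration,
Welch against Parseval, t/r statistics against closed-form formulas, and
BH selection against the step-up procedure by hand.

Statistical behavior is verified by simulation at sizes chosen to keep the
default test run comfortably under half an hour on one CPU: calibration
cohorts use 15 subjects, 100 Hz, 5 s recordings (the quadratic entropy
step makes recording length the main cost driver; 500 samples per band
already saturate the m = 2 entropies), 20 cohorts for the 640-cell
false-positive rate, 100 replicates at 200 permutations for the
permutation-test rejection rate, and 20 cohorts of 30 subjects for
planted-effect recovery. The same studies are recomputed from scratch by
`scripts/acceptance.R` at every run.

## Known limitations

* The uncorrected default selection is faithful to exploratory practice
  but optimistic; use `correction = "BH"` or `selection = "nested"` for
  anything confirmatory.
* The amplitude-threshold artifact screen does not remove in-band
  physiological artifacts the way ICA can.
* Entropy features depend on `m`, `r`, and series length; comparisons are
  only meaningful within a fixed parameter set.
* The montage geometry used for topographies is schematic; maps are for
  qualitative channel-level inspection, not source localization.
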