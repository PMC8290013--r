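---
title: "Frontal-midline theta: models, simulation and decoding methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal-midline theta: models, simulation and decoding methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`fmtheta` analyses frontal-midline theta (4–8 Hz) oscillations as an index of
cognitive-control demand, across four control strategies — proactive control,
reactive control, inhibitory control and response conflict — each contributing
a low-demand *control* and a high-demand *target* condition. The analysis
chain is:

1. **Time–frequency decomposition.** Each epoch is convolved with complex
   Morlet wavelets `exp(i 2πft) · exp(−t²/(2σ²))`, with `σ = s/(2πf)` and an
   adaptive cycle count `s` rising linearly from 3 at 1 Hz to 10 at 25 Hz.
   Power is `Re(z)² + Im(z)²`; event-related spectral perturbation (ERSP) is
   `10·log10(power(t)/power(baseline))` with a −500…−200 ms divisive baseline
   computed on the trial-averaged power; inter-trial coherence (ITC) is the
   modulus of the across-trial mean unit phasor.
2. **ROI summarization.** Scalar theta indices average ERSP/ITC over
   Fz/FCz/Cz × 4–8 Hz × 200–450 ms; single-trial theta power time courses at
   the three sensors are the decoding features.
3. **Decoding.** For each ordered pair of strategies (16 pairs), a linear
   discriminant is trained to separate control from target trials of the
   training strategy and evaluated on the test strategy, per timepoint on a
   0–1000 ms / 20 ms grid, with class-equalizing subsampling, fivefold
   cross-validation and three repetitions. Group inference is a two-sided
   one-sample t-test against 0.5 per pair × timepoint, with one
   Benjamini–Hochberg correction over all 816 p-values.
4. **Statistics.** Behavioral interference scores (control − target accuracy;
   target − control RT, absent for inhibitory control), repeated-measures
   ANOVAs with Greenhouse–Geisser correction and partial η², Bonferroni
   post-hocs, and residualized Pearson correlations between theta and
   behavior.

## The synthetic generator

No public data accompany this design, so the generator is a first-class,
tested module that emulates the statistical structure the analyses assume:

- **Background noise** is 1/f ("pink") noise, synthesized by shaping white
  spectra by `f^(−α/2)` (default α = 1) and normalized so its SD equals the
  configured amplitude (default 10 µV), a typical broadband EEG level.
- **The theta burst** is a Gaussian-windowed 6 Hz sinusoid centered midway
  through 200–450 ms with envelope SD `(offset − onset)/4`. This closed form
  makes the dB and ITC oracles exact: an amplitude ratio *r* between
  conditions must recover `20·log10(r)` dB, and zero phase jitter must give
  ITC = 1.
- **Phase consistency** is controlled by a wrapped-normal per-trial phase
  offset (SD in radians); target trials default to tighter locking (0.7 rad)
  than control trials (1.2 rad).
- **Topography** is a per-channel gain peaked at FCz; only a labeled sensor
  subset is simulated, not a realistic high-density montage.
- **Trial counts** are drawn per condition from normal distributions with the
  heterogeneous means/SDs characteristic of this multi-task design (the
  shared low-control condition makes proactive/reactive control trials ~4–13×
  more numerous than their targets), rounded and clipped at the 10-trial
  inclusion floor. This heterogeneity is what motivates the
  count-equalizing subsampling before ITC comparisons.
- **Behavior** follows condition mean + subject effect + coupling ×
  (subject theta effect) + noise. Each subject has a latent theta target
  effect `u` that multiplicatively modulates target burst amplitude and
  enters the target-condition behavioral residual with weight ρ
  (`behavior_coupling`), so the population residualized theta–behavior
  correlation equals ρ. Accuracy means are patterned on the large
  reactive/inhibitory, moderate conflict, small proactive interference
  ordering typical of these tasks; the sign of the coupling is applied
  identically to accuracy and RT for testability.

**Effect-size calibration.** Published effect sizes for these contrasts are
reported as statistics, not dB, so the default target amplitude (9.7 µV peak
envelope vs 4 µV control, on 10 µV noise) was calibrated once so that the
*measured* ERSP contrast at the midline ROI is ≈ +2 dB — a realistic
magnitude for frontal-midline theta — and then frozen. With noise present,
the measured dB contrast is smaller than the noise-free
`20·log10(A_t/A_c)` because the noise floor enters both powers.

**What the generator does not emulate:** ocular/muscle artifacts, channel
rejection and interpolation, ICA structure, volume conduction, realistic
cross-channel noise correlation, or non-stationary drift. Passing tests
therefore show the pipeline's correctness and calibration on well-specified
oscillatory data, not robustness to real-world artifacts.

## Numerical choices

- **Wavelet kernels** are truncated at ±3σ and not amplitude-normalized:
  normalization cancels in the dB ratio and does not affect phase. The
  printed-form ambiguity in some descriptions of the Morlet wavelet (sign of
  the Gaussian exponent, presence of the imaginary unit) is resolved to the
  standard decaying complex form.
- **Edge handling**: coefficients within 3σ of the lowest analyzed frequency
  from either epoch boundary are flagged invalid; ROI extraction refuses
  windows overlapping them. The long epochs (−2500…+3000 ms) exist precisely
  to keep the −500…+1000 ms analysis range clean at 1 Hz.
- **Convolution** is frequency-domain multiplication with "same" alignment,
  vectorized over channels × trials.
- **Baseline convention**: the divisive baseline uses trial-averaged power,
  then the log. Per-trial log-baselining is a known alternative; the
  trial-average-first convention is fixed here.
- **Decoding grid**: 20 ms steps do not align with the 8 ms sample period at
  125 Hz, so each nominal timepoint snaps to the nearest sample (recorded in
  the grid metadata); no interpolation.
- **Decoding features** are single-trial linear theta power (not
  dB-baselined), z-scored per sensor with pooled statistics across both
  classes. The discriminant is invariant to per-feature affine maps, so this
  is purely numerical conditioning and introduces no label leakage.
- **LDA regularization**: the pooled covariance is shrunk toward its diagonal
  with fixed coefficient 0.05 — necessary for small subsampled training
  folds; exact ties in the decision score break toward the
  lexicographically lower label.
- **Cross-strategy fold semantics**: both strategies' equalized trial sets
  are partitioned into five folds; fold *j* trains on the training strategy's
  other folds and tests on the test strategy's fold *j*. This keeps the
  "3 repetitions × 5 folds" scheme uniform across all 16 analyses, including
  same-strategy decoding where fold disjointness is mandatory. (The
  alternative — training on all training-strategy trials when strategies
  differ — would use 25% more training data in 12 of 16 analyses at the cost
  of a non-uniform procedure.)
- **Decoding subsampling** is independent of the global eight-condition
  equalization used for the ITC/ERSP scalars: the scalar summaries equalize
  across all eight conditions (ITC is biased by n), while decoding equalizes
  the two classes per pair, fresh per repetition.
- **Greenhouse–Geisser epsilon** is the standard estimator from the sample
  covariance of orthonormalized within-subject contrasts, clamped to
  `[1/(k−1), 1]`; both numerator and denominator dfs are multiplied by it.
  η² values are partial: `SS_effect / (SS_effect + SS_error)`.
- **Degenerate inputs**: completely flat response matrices report F = 0 /
  p = 1; a zero error SS with a nonzero effect SS reports F as absent with a
  warning; zero-variance accuracy cells at exactly 0.5 get p = 1; a
  zero-variance residualization predictor returns centered targets with a
  message.
- **Seed lineage**: every stochastic stage (subject generation, subsampling,
  equalization, folds, repetitions) derives its stream deterministically from
  the master seed and structural indices, so the full pipeline is
  reproducible end-to-end and any subject is regenerable in isolation.

## Type-I calibration of the rm-ANOVA

The null-simulation check generates compound-symmetric (spherical) data, for
which the uncorrected F-test is exactly calibrated; the test suite asserts
its rejection rate is 0.05 within Monte-Carlo error over 2000 simulated
studies of 12 subjects. Under sphericity the Greenhouse–Geisser correction is
known to be conservative (ε̂ < 1 even when ε = 1), so its rejection rate is
asserted to be at most nominal + Monte-Carlo error rather than equal to
nominal; on spherical data an equality assertion would test the estimator's
small-sample bias, not error control.

## Problem sizes

The packaged checks run at desk scale, chosen once: chance calibration uses
20 subjects × 60 trials/condition; the generalization check 30 subjects; the
coupling-recovery check 176 subjects (behavior-only, using the generator's
ground-truth theta amplitudes — the EEG-derived path is property-tested at
small n); type-I calibration 2000 studies of 12 subjects. The wavelet grid
for pipeline theta features defaults to the 4–8 Hz bins; since each
frequency is decomposed independently, theta summaries are identical to
those extracted from the full 1–25 Hz grid.

## Container and interfaces

Studies persist in a directory container: `meta.json` (schema version,
package version, full configuration), `subjects/sub-XXX/epochs_*.rds` (one
array per condition with times/fs/channel labels), `behavior.csv`, and
`derived/` tables (theta scalars, decoding group statistics, interference,
correlations) plus `report.md`. Validation refuses mismatched schema
versions and names missing fields. The command-line wrapper
(`inst/cli/fmtheta.R`) exposes `simulate`, `run` and `report`; the finer
stages (wavelets, ROI, decoding, statistics) are ordinary package functions,
which is the natural staging interface in R.

## Known limitations

- The generator's burst is strictly stimulus-locked and oscillatory;
  induced (non-phase-locked) activity is only represented through phase
  jitter, and no strategy-specific theta differences are simulated by
  default (all four strategies share burst parameters).
- The behavioral model is linear-Gaussian with clipping at the accuracy
  bounds; heavy clipping (very high means with large SDs) attenuates the
  recovered coupling.
- Decoding uses exactly the three midline sensors; no searchlight or
  whole-scalp decoding.
- ITC subsampling uses one seeded draw (the decoding stage's three-repetition
  averaging is separate and explicit).
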