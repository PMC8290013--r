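# fmtheta

Simulation and analysis of **frontal-midline theta** (4–8 Hz) EEG dynamics
across four cognitive control strategies — proactive control, reactive
control, inhibitory control and response conflict — each contributing a
low-demand *control* and high-demand *target* condition. The package is
aimed at cognitive neuroscientists who want a reproducible, testable
implementation of the standard theta analysis chain and of cross-strategy
decoding, driven by a synthetic generator when no real recordings are at
hand.

## What it computes

- **Time–frequency decomposition** with complex Morlet wavelets
  `exp(i2πft)·exp(−t²/2σ²)`, `σ = s/(2πf)`, cycles `s` ramping linearly from
  3 (1 Hz) to 10 (25 Hz).
- **ERSP**: `10·log₁₀[power(t)/power(baseline)]`, baseline −500…−200 ms.
- **ITC**: `|n⁻¹ Σₓ e^{iφₓ}|`, the across-trial mean resultant length, with
  trial-count-equalizing subsampling across the eight conditions.
- **Theta ROI summaries** over Fz/FCz/Cz × 4–8 Hz × 200–450 ms.
- **16-way cross-strategy decoding**: a regularized linear discriminant
  trained on control-vs-target trials of one strategy and tested on another
  (or the same) strategy, per timepoint (0–1000 ms, 20 ms grid), with class
  equalization, fivefold cross-validation, 3 repetitions, and group-level
  one-sample t-tests against chance (0.5) under one Benjamini–Hochberg FDR
  correction over all 16 × 51 p-values.
- **Statistics**: behavioral interference scores (control − target accuracy;
  target − control RT), repeated-measures ANOVAs with Greenhouse–Geisser
  correction and partial η², Bonferroni post-hocs, and residualized Pearson
  correlations linking theta to individual differences in performance.
- **Synthetic studies**: 1/f noise + a midline-peaked, Gaussian-windowed
  6 Hz burst whose amplitude and phase locking differ between control and
  target trials, heterogeneous per-condition trial counts, and behavioral
  scores coupled to each subject's theta effect at a configurable strength.

## Worked example

```r
library(fmtheta)

tc <- default_trial_counts(); tc$mean <- 60; tc$sd <- 0
cfg <- simulation_config(n_subjects = 4, trial_counts = tc, seed = 42)
rep <- run_pipeline(cfg)

subset(rep$scalars, subject == 1)[, 1:4]
#>     strategy trial_type theta_power theta_itc
#> 1  proactive    control   0.7574427 0.1914359
#> 2  proactive     target   3.0574256 0.5481407
#> 3   reactive    control   0.7417330 0.2119692
#> 4   reactive     target   3.5198701 0.5090933
#> 5 inhibitory    control   0.3715452 0.1540810
#> 6 inhibitory     target   3.2781099 0.5954171
#> 7   conflict    control   0.6268719 0.1249088
#> 8   conflict     target   3.0094682 0.5670936

mean(rep$decoding)                      # grand-mean decoding accuracy
#> [1] 0.5800449
head(decoding_window_accuracy(rep), 3)  # group accuracy in 200-450 ms
#>       train       test window_accuracy
#> 1 proactive  proactive       0.7270833
#> 2 proactive   reactive       0.7729167
#> 3 proactive inhibitory       0.7625000
```

The grand mean (0.58) averages over the whole 0–1000 ms grid, most of which
precedes or follows the burst; within the 200–450 ms window accuracies reach
0.72–0.77.

Target trials carry ≈ +2 dB more midline theta than control trials in
200–450 ms (the generator's default), so every train/test pairing decodes
control from target well above the 0.5 chance level in that window, and the
scalar table shows the corresponding theta power (dB) and phase-locking
(ITC) increases for target conditions. With `null_config(cfg)` the same
pipeline sits at chance.

A command-line wrapper is included:

```sh
Rscript inst/cli/fmtheta.R run --path study/ --seed 42
Rscript inst/cli/fmtheta.R report --path study/
```

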