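# blinkfuse

Decoding task conditions from EEG by fusing brain activity with the eye
blinks embedded in the same recording.

Spontaneous eye blinks are not just artifacts: the blink component extracted
from multichannel EEG carries information about cognitive state, and the
evoked EEG response that follows each blink peaks at a task-dependent
latency. `blinkfuse` implements a synchronization-based fusion pipeline for
blink-locked EEG:

1. **Blink extraction** — identify the blink component in a channel
   decomposition (largest positive Pearson correlation between its left and
   right anterior back-projections), detect blink peaks where the component
   exceeds its mean by 1.5 SD, cut epochs from −500 to +1000 ms around each
   peak, and iteratively reject artifact epochs (absolute threshold 500 µV or
   an SD z-score above 5, at most 10% of epochs per iteration).
2. **Synchronization** — compute the global field power (GFP) of the average
   blink-locked response, `GFP(t) = sd_channels(mean_epochs(x))`, locate its
   post-blink maximum, and estimate the offset
   `Δt = t_GFP_max − t_blink_max` per condition; per-participant alignment
   uses the mean offset across conditions, and the blink series is shifted
   into register with the evoked response.
3. **Fusion** — reduce the EEG epochs to the principal components capturing
   95% of the variance (`pcEEG`), then either concatenate them with the
   aligned blink series (`pcEEG+`) or fuse via canonical correlation
   analysis, solving
   `S_xx⁻¹ S_xb S_bb⁻¹ S_xbᵀ u = ρ² u` and stacking the canonical variates.
4. **Decoding** — slide a 50 ms window (13 samples at 250 Hz) over the
   epochs, flatten series × samples per trial (5 PCs → a 65 × n_trials
   feature matrix; +1 blink series → 78 × n_trials), balance classes by
   downsampling, and run five-repetition 80/20 cross-validation with
   train-set-only z-scoring and a linear SVM. Metrics are
   `Acc = 100(TP+TN)/N`, `Sen = 100·TP/(TP+FN)`, `Spe = 100·TN/(TN+FP)`,
   macro-averaged one-vs-rest for more than two classes. Temporal
   generalization matrices evaluate every train-window classifier at every
   test window.
5. **Statistics** — pointwise paired t-tests with Benjamini–Hochberg FDR
   correction, and an extreme-pixel permutation test (1,000 sign-flip
   permutations; a pixel is significant beyond the 99.5th percentile of the
   permuted maxima or the 0.5th percentile of the minima).

Because blink-locked recordings of this kind are rarely shareable, the
package ships a fully parameterized synthetic generator
(`sim_config()`, `simulate_recording()`, `simulate_epochset()`) with ground
truth for every stage: blink times, mixing matrix, and the true per-condition
blink-to-GFP lags.

## Worked example

```r
library(blinkfuse)

cfg <- sim_config(n_channels = 30, conditions = c("stand", "walk"),
                  evoked_lag = c(stand = 148, walk = 172),
                  blink_amp_by_condition = c(stand = 1, walk = 1.25),
                  snr = 1.2, seed = 42)
rc  <- run_config(sim = cfg, methods = c("pcEEG+", "pcEEG", "syncBlink"),
                  n_epochs_per_condition = 80, step_samples = 20, seed = 42)
run <- run_pipeline(rc)
run
#> <blinkfuse_run: P01 | 160 balanced epochs>
#>   pcEEG      peak 68.1% at 164 ms
#>   pcEEG+     peak 87.5% at 164 ms
#>   syncBlink  peak 86.9% at 164 ms

run$offsets[, c("condition", "delta_t_ms", "delta_t_samples")]
#>   condition delta_t_ms delta_t_samples
#> 1     stand        144              36
#> 2      walk        172              43
#> 3    pooled        158              40
```

The true lags were 148 and 172 ms; the GFP-based estimates land within one
sample (4 ms) of each. The two conditions differ both in evoked latency
(EEG information) and blink amplitude (ocular information): at this noise
level each single stream decodes imperfectly, while the fused `pcEEG+`
stream beats both. `autoplot(run$curves)` draws the paired decoding curves;
`temporal_generalization()` and `extreme_pixel_permutation()` extend the
analysis to train × test time matrices with family-wise inference.

All user-facing results are tibbles, fitted objects have `tidy()` /
`glance()` methods, and each result type has an `autoplot()`. A thin CLI
wrapper lives at `inst/cli/blinkfuse` (subcommands `simulate`, `extract`,
`sync`, `run`).

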