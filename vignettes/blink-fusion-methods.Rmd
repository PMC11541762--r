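---
title: "Synchronization-based fusion of EEG and eye blinks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization-based fusion of EEG and eye blinks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkfuse)
```

# The problem

Multivariate pattern analysis of EEG usually treats eye blinks as artifacts
to be removed. `blinkfuse` takes the opposite stance: the blink component of
a channel decomposition is itself an informative physiological signal, and
the evoked EEG response that follows each blink peaks at a latency that
depends on what the person is doing. The package decodes task conditions
from blink-locked epochs by fusing two streams extracted from the same
recording — the EEG principal components and the blink component shifted
into temporal register with the post-blink evoked response.

# The model, stage by stage

## Blink extraction

The decomposition is pluggable: a user-supplied unmixing matrix (e.g. from
any ICA tool), or the package's symmetric fixed-point ICA
(`decompose_components()`, whitening plus orthogonalized tanh-contrast
updates). We deliberately do not reimplement a full IC taxonomy; eye
candidates come from ground truth (simulations), a supplied label file, or a
frontal-topography heuristic. Among eye candidates the blink component is
the one whose left and right anterior back-projections correlate most
positively: blinks drive both frontal channels with the same polarity,
horizontal saccades with opposite polarity. Note that back-projecting a
single component yields correlations of exactly ±1, so the rule is
effectively a polarity test; it still separates blink-like from saccade-like
candidates cleanly.

Blink peaks are samples where the component exceeds its overall mean by 1.5
standard deviations; each contiguous supra-threshold run of at least 50 ms
yields one event at the run maximum, and events closer than 200 ms are
merged (the larger peak wins). The duration and refractory guards are our
additions — without them a noisy pulse double-counts. A zero-variance signal
yields an empty event series rather than an error, because downstream code
treats "no blinks" as an empty result, not a crash.

Epochs run from −500 to +1000 ms around each blink peak with inclusive
endpoints, so 376 samples at 250 Hz with time 0 exactly on the blink-peak
sample. Artifact rejection iterates two rules: any sample beyond 500 µV in
magnitude, or a per-epoch SD whose z-score against the across-epoch SD
distribution (per series, max over series) exceeds 5. At most
`floor(0.10 · n)` epochs (at least one, if any violate) are removed per
iteration, worst offenders first, and the SD statistics are recomputed after
every pass. The z-score definition is our choice — a bare "SD threshold of
5" is not a complete statistic; z-scoring against the epoch population makes
the rule scale-free. The procedure is idempotent by construction: it stops
exactly when no epoch violates either rule.

## Synchronization

GFP is the Lehmann–Skrandies definition: at each time point, the population
standard deviation across channels of the epoch-averaged signal. It is
invariant to channel permutation and to adding a common offset across
channels at one instant. The GFP peak is searched in 0–500 ms after the
blink peak, where the blink-evoked response lives; a peak on the search
boundary is flagged as possibly truncated. The offset is
`Δt = t_GFP_max − t_blink_max`, with `t_blink_max` re-estimated from the
mean blink trace (≈ 0 by epoch construction). Offsets are estimated per
condition and averaged per participant; the pooled value is what alignment
uses. Estimating Δt from all of a participant's epochs mixes training and
test trials in the later decoding stage; we follow that convention as the
default (it mirrors how such pipelines are run in practice) and expose
fold-wise refitting of PCA as an option for users who want strict
separation — the leakage affects a single scalar per participant and, in our
simulations, does not move decoding accuracy measurably.

Two shift primitives exist because the conventional shift formula and the
purpose of synchronization disagree about sign. `shift_blink()` applies the
formula as usually written, `BC_sync(t) = BC(t + Δt)`, which *advances* the
signal (`[0,1,2,3]` shifted by +1 sample becomes `[1,2,3,3]` with edge
replication). But advancing the blink moves its pulse *away* from the
GFP-peak windows, which defeats the point of aligning the streams — with an
advanced blink, fused features never contain blink and evoked information in
the same 50 ms window. `align_blink()` therefore applies the estimated
offset in the registering direction (`BC(t − Δt)` for positive Δt), which
places the blink peak on the GFP peak; the pipeline uses `align_blink()`.
Edge-vacated samples are filled by replicating the edge value (zero-fill is
available); replication avoids a step inside the feature windows.

## Fusion

PCA is fit on the `(epochs · times) × channels` matrix after per-channel
mean removal, per participant, and the smallest k with cumulative explained
variance ≥ 95% is retained (tie broken toward fewer components; loadings
signed so the largest-magnitude weight is positive, for run-to-run
reproducibility). `pcEEG+` row-stacks the k PC series with the single
aligned blink series per epoch.

CCA between the EEG channels and the aligned channel-space blink solves the
eigenproblem `S_xx⁻¹ S_xb S_bb⁻¹ S_xbᵀ u = ρ² u` (and its v counterpart),
with a ridge term `ε · trace/dim`, ε = 1e-8, added to each autocovariance —
the covariances of a back-projected single component are exactly rank-1, so
unregularized inversion would fail; the error message names the remedy.
Weights are normalized to unit variance (`uᵀS_xx u = 1`), pairs sorted by
descending ρ, one pair kept by default. The fusion equation for CCA is
written in terms of the weight vectors `[u; v]`, but trial-wise features are
what a classifier needs, so we take the operational reading: the canonical
*variates* `X'(t) = uᵀX(t)` and `B'(t) = vᵀB(t)` are stacked per epoch (two
series per pair). Both the weights and the variates are exported.

## Decoding

Feature assembly: a 50 ms moving window — `ceiling(w · fs / 1000)` rounded
up to an odd count, 13 samples at 250 Hz — slides over the epoch at a
1-sample (4 ms) stride, and `series × in-window samples` are flattened per
trial. With 5 PCs and 500 trials the EEG feature matrix is 65 × 500; adding
the aligned blink makes it 78 × 500. Classes are balanced by downsampling
the majority class (for one-vs-rest contrasts: pool first, then balance).
Cross-validation is five stratified random 80/20 splits; features are
z-scored with train-set means and SDs only (a zero-SD feature gets scale 1
and is counted in the result), and a linear SVM with C = 1 (one-vs-rest
ensemble for k > 2, macro-averaged metrics) produces test confusion counts.
For balanced k-class data the macro metrics satisfy
`Sen = Acc` and `Spe = 100 − (100 − Acc)/(k − 1)`, which the tests use as an
implementation self-check. Sensitivity with no positive trials is reported
as `NA` with a warning, never as silent zero.

The temporal generalization matrix trains at every window and tests at every
window using the same folds and the training window's normalization
parameters; with shared folds its diagonal reproduces the sliding-window
curve exactly, and all methods within one `run_pipeline()` call see
identical trial splits so contrasts are paired.

## Statistics

Curve contrasts use two-sided paired t-tests per time point with
Benjamini–Hochberg step-up FDR (Benjamini–Yekutieli available); zero-
variance differences give flagged `NA` p-values. Family-wise inference on
TGM difference maps uses the extreme-pixel permutation test: each of 1,000
permutations flips the sign of every participant's map (the paired-design
equivalent of reallocating participants between groups), and the maximum and
minimum pixel of each permuted mean map form the null distributions. The
two-tailed level is α = 0.01: observed pixels beyond the 99.5th percentile
of the maxima or the 0.5th percentile of the minima are significant. The
extreme-pixel mask is always a subset of the pointwise-uncorrected mask.

# The synthetic generator

`sim_config()` describes the recording the package is designed for: 30
channels in a 10–20 montage at 250 Hz, ~100 µV frontal blink pulses
(100 ms half-cosine rise, 200 ms fall — the asymmetric unipolar morphology
the 1.5 SD detector assumes) at 12 blinks/minute with lognormal amplitude
variability, and a posterior Hann-windowed 10 Hz burst whose envelope
maximum sits `delta_t_true` ms after each blink peak. Default lags are
148/168/188 ms across three conditions — on the 4 ms sample grid
deliberately, so that lag recovery is not confounded by placement rounding,
and bracketing the post-blink decoding apex range reported for tasks of this
kind. Conditions are simulated as interleaved blocks tagged per blink.

Noise is spatially structured: six background sources with random fixed
topographies and geometrically decaying amplitudes (ratio 0.75), 1/f-shaped
by default, plus a 5% spatially white sensor floor. The low spatial rank is
essential, not cosmetic: real EEG background is dominated by a few strong
sources, which is precisely why a 95%-variance rule retains a handful of
components (typically 5–7 here) rather than all channels. With spatially
white noise the same rule would retain nearly every channel and the
principal-component representation would be meaningless. `snr` is the evoked
peak amplitude divided by the average per-channel noise SD.

The EEG epochs emitted by `simulate_epochset()` represent the
post-component-cleaning view — evoked response plus background, with the
ocular artifact carried separately as the blink-component stream — mirroring
a pipeline in which non-brain components are removed from the EEG while the
blink component is kept as its own signal. Without this, the ~100 µV blink
artifact would dominate the GFP inside the 0–500 ms search window and the
estimated offset would be 0 for every condition.

What the generator does *not* emulate: head-model lead fields, saccade and
muscle artifact classes, nonstationary noise, electrode drift, or realistic
blink kinematics beyond the pulse shape. Passing tests on these simulations
therefore demonstrate that the algorithms recover their own ground truth
under EEG-like statistics — not that any particular empirical accuracy level
will be reached on recorded data.

# Numerical choices

- Epoch grid: inclusive endpoints, time 0 on the grid; sample indices are
  1-based in R (the −500..1000 ms window at 250 Hz spans 376 samples).
- Offset quantization: `round(Δt · fs / 1000)` samples, sign preserved.
- PCA: tie-break toward fewer components at exactly 95%; sign convention
  largest-|loading| positive; selection threshold compared with a 1e-12
  slack so floating-point cumulative sums cannot drop a component.
- CCA: ridge ε = 1e-8 relative to `trace/dim`; eigenvectors re-orthogonalized
  against the metric via explicit normalization; ρ clipped to [0, 1].
- SVM decision values are computed from the primal weights (`w = Σ αᵢ yᵢ xᵢ`)
  rather than through repeated kernel evaluations, with an orientation check
  against the training labels, so one-vs-rest scoring over hundreds of
  windows stays fast and deterministic.
- All randomness (simulation, balancing, folds, permutations) flows through
  seeded private RNG streams; child seeds are derived arithmetically from the
  master seed and stay below 2³¹.

# Test problem sizes

The suite exercises the pipeline at sizes chosen to make every property
measurable in seconds to a couple of minutes: 100 epochs per condition for
offset recovery (the averaging the GFP estimate needs), 10 seeds × 100
epochs per condition for the fusion-dominance property (12 channels,
condition lags 148 vs 172 ms, blink amplitude ratio 1.25, snr 1.5 — a regime
where each single stream decodes well above chance but below ceiling, so a
strict fusion gain is detectable), and a 200-run nested null with 200
permutations each for the family-wise error check. These are the package's
own desk-scale study conditions; the algorithms contain no size-dependent
switches.

# Known limitations

- The blink-component identification rule is a polarity test under pure
  back-projection; decompositions whose eye candidates mix blink and saccade
  activity in one component will defeat it.
- Δt is a per-participant constant; per-trial offset estimation is out of
  scope by design (single-epoch GFP is too noisy for argmax estimation).
- The decoder is a linear SVM with fixed C = 1; no kernels, no
  hyperparameter search. C is exposed for users who want to vary it.
- The extreme-pixel permutation implements the two-condition paired design;
  omnibus designs across three or more methods are handled pairwise.
- File I/O is plain text (delimited recordings and matrices, CSV events and
  epoch containers, JSON manifests).
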