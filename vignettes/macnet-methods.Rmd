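---
title: "Decoding lower-limb motor imagery with an attention-enhanced shallow ConvNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding lower-limb motor imagery with an attention-enhanced shallow ConvNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement without executing
it — modulates the sensorimotor mu rhythm (≈ 7–13 Hz): when the
corresponding cortical area activates, mu band power *drops* relative to a
resting baseline (event-related desynchronization, ERD).  Lower-limb MI is
unusually hard to decode: the leg representation sits medially and deep in
the interhemispheric fissure, so scalp signals are weak, focal, and easily
buried in noise.  This package implements a four-class decoder for the
tasks sit-to-stand (`S-ST`), stand-to-sit (`ST-S`), `walking`, and
`standing` (the baseline that retains full mu power), together with the
full preprocessing, training, evaluation and experiment pipeline, and a
synthetic ERD-structured EEG generator so every stage runs and is tested
without access to recording hardware or restricted subject data.

## The model

`macnet_config()` / `macnet_init()` build a shallow-ConvNet backbone
augmented with two attention stages ("MACNet"):

1. **Temporal refining** (`temporal_attention()`): single-head scaled
   dot-product self-attention in which the `T = 250` time points are the
   tokens and the `C = 61` electrodes the embedding:
   `Q = X'W_Q'`, `K = X'W_K'`, `V = X'W_V'`,
   `A = rowsoftmax(QK'/sqrt(d))` with `d = C`, added residually,
   `X~ = X + (AV)'`.  There is no positional encoding; temporal order
   enters only through the content of the tokens.
2. **Temporal convolution**: 40 filters of size (1, 25), stride 1, valid
   padding (250 → 226 time points) — a learnable band-pass bank.
3. **CBAM** (`apply_cbam()`): a channel gate (global average- and
   max-pooled descriptors through a shared 2-layer MLP with bottleneck
   `floor(40/16) = 2`, summed, sigmoid) followed by a spatial gate
   (feature-map mean/max descriptors, same-padded 7×7 convolution,
   sigmoid), applied multiplicatively and wrapped in a residual skip:
   `F + Ms(F') ⊗ F'` with `F' = Mc(F) ⊗ F`.
4. **Spatial convolution**: 40 filters of size (61, 1) collapse the
   electrode axis — learned spatial filters in the CSP tradition.
5. **Log-power head**: affine-free batch normalization, elementwise
   square, average pooling (1, 75) stride (1, 15) (226 → 11), dropout 0.3,
   and a safe log `log(max(x, 1e-6))`.  Square → mean-pool → log computes
   smoothed log band power of each learned spatial filter.
6. **Classifier**: a (1, 11) convolution consumes the pooled axis exactly,
   giving 4 logits, softmax, cross-entropy.

Branch `"0"` is the plain backbone (stages 2, 4–6), branch `"I"` adds the
temporal refining stage, branch `"II"` is the full model.  With the
published geometry the branches hold 100,444 and 111,908 learnable scalars
(100.44 K / 111.91 K).

Three published-count pins fixed otherwise-open conventions: the attention
projections are bias-free **and** include a learnable value projection
(the literal equations set `V` to the input sequence; a config flag
`value_projection = FALSE` restores that reading), and batch
normalization carries no learnable affine pair.  With biased projections,
or an affine BN, or no `W_V`, no combination reproduces both published
budgets; the chosen convention misses the full-model figure by only 12
scalars (0.011%).  The square nonlinearity before pooling is likewise a
judgment call (`square_before_pool`, default on): a safe log directly on
signed BN outputs would discard sign information, and the shallow-ConvNet
lineage this head descends from squares first.

### Numerical choices

* Attention scores are scaled by `sqrt(d)` with `d = 61`, the transformer
  convention; softmax subtracts the row maximum.
* `safe_log_eps = 1e-6`; BN epsilon `1e-5`; degenerate (constant) samples
  min–max normalize to all-zeros rather than erroring.
* Weights draw from Glorot-uniform fan-based limits; all randomness
  (initialization, shuffling, dropout, the generator) flows from explicit
  integer seeds, so every result in the test suite is bit-reproducible.
* The training engine is single-precision C++ (Armadillo/BLAS); the
  exported per-operation R functions are double precision and every engine
  path is cross-checked against them (tolerance 1e-4) and against
  independent loop oracles (1e-8), plus central-difference gradient checks.

## Training and evaluation

`macnet_train()` runs mini-batch Adam (`lr = 1e-4` default) under cosine
annealing (one period over the run, no restarts), with an
exponential-moving-average (EMA) shadow of all weights (`decay = 0.999`)
updated every step and used for evaluation.  The EMA is *zero-debiased*
(divided by `1 - decay^step`): on desk-scale runs of a few hundred steps an
uncorrected shadow would still be dominated by its zero initialization.

`tenfold_cv()` / `kfold_cv()` partition **trials**, not windows, by
default: the five windows cut from one trial are near-duplicates, and
letting them straddle the train/test boundary inflates accuracy.
`split_mode = "sample"` mirrors the laxer protocol.  Folds are stratified
by class and globally balanced.  `accuracy_pct()`, `cohens_kappa()` and
`wilcoxon_signed_rank()` implement the evaluation statistics; kappa is the
standard chance-corrected `(P0 − Pe)/(1 − Pe)`, and the signed-rank test
uses the exact sign-flip null distribution for n ≤ 25 pairs (computed by
generating-function convolution over midranks, so it remains exact under
ties) with zero differences dropped first.

## The synthetic generator

`generate_recording()` emulates one session of the acquisition protocol:
64 channels (10–20 montage including mastoids `M1`/`M2` and one `EOG`) at
1000 Hz, balanced randomized trials of 5 s imagery separated by 5 s gaps,
event markers at each imagery onset.  Its components, and the reasoning
behind them:

* **Background**: Gaussian `1/f` noise (frequency-domain synthesis),
  10 µV RMS per channel — the canonical resting EEG spectrum.
* **Mu rhythm**: a narrowband oscillation on the sensorimotor strip
  (`Cz, C1–C4, FCz, CP1, CP2`).  The peak frequency is a stable individual
  trait, so it is drawn once per session (±0.1 Hz trial wander), and the
  oscillation reaches all electrodes from a single effective source with a
  common phase (volume conduction is instantaneous at EEG frequencies).
  Amplitude is set by `snr`, the full-amplitude oscillation-to-background
  variance ratio.
* **ERD**: during non-standing imagery the mu amplitude is scaled by
  `1 − erd_depth · m(channel)`, where the per-class profile `m` gives each
  class a distinct spatial *shape*: walking is midline-focal (the
  lower-limb representation is medial), sit-to-stand and stand-to-sit are
  left- and right-lateralized, standing keeps full power.  Power ratios
  are therefore exactly `(1 − erd_depth·m)²` — walking vs standing at Cz
  is `(1 − 0.5)² = 0.25` at the default depth.
* **Posterior alpha**: a class-independent oscillation at full amplitude
  over O/PO sites.  Besides realism, it anchors the per-sample min–max
  normalization scale; without it the motor mu itself sets the sample
  maximum and normalization would cancel the very amplitude contrast the
  decoder must find.
* **EOG**: 0.25–1 s half-sine blinks (80–150 µV) on the EOG channel only,
  which preprocessing discards.

What the generator does **not** emulate: biophysical forward modeling,
spatially correlated noise, movement artifacts, inter-subject variability,
ERD time courses within a trial, or phase lags between channels.  Passing
tests on this data therefore demonstrate that the pipeline and model
recover a planted, physiologically shaped ERD pattern — not that the model
reaches any particular accuracy on real recordings.

## Experiments

`run_ablation()` trains branches 0/I/II under identical seeds and fold
partitions; `run_channel_reduction()` evaluates nested center-out channel
subsets (sensorimotor strip first — the subsets are this package's choice,
as no canonical nesting exists); `run_module_removal()` compares the
backbone with its temporal- or spatial-convolution stage removed (the
classifier re-sizes to the resulting geometry); `audit_complexity()`
counts parameters and multiply–accumulates analytically from the
configuration (one MAC per multiply–add in convolutions, linear layers and
the attention matrix products; softmax and elementwise gates ignored —
conventions differ enough between published counters that MAC figures are
reported, never asserted) and can time the batched forward pass.
`psd_topography()` integrates Welch spectra (1 s Hann segments, 50%
overlap) over 7–13 Hz per channel; `diff_map()` of a non-standing
condition minus standing is negative over the motor strip and near zero
elsewhere — the ERD topography signature.

## Desk-scale problem sizes

The published protocol (20 sessions × 60 trials per subject, tenfold CV,
300 epochs) is far beyond a package test suite.  The suite instead fixes
these sizes, chosen up front by budget arithmetic: oracle checks run at
toy geometry (C ≤ 5, T ≤ 30); pipeline checks use 2–8 trials; the
classification-recovery check uses 24 trials (120 windows) at high SNR
(`snr = 25`, `erd_depth = 0.5`), 3-fold trial-level CV, 50 epochs, and a
batch size of 4 so that the Adam step count matches what the full-scale
protocol would take at batch 64.  Because a 50-epoch desk run offers ~25×
fewer optimization steps than the 300-epoch full protocol, the recovery
runs scale two schedule-linked settings to the shortened run: the learning
rate (the step-size × step-count product, not the step size, is what a
compressed cosine schedule must preserve — `1e-3` at desk scale; `1e-4`
remains the package default for full-scale training) and the EMA decay
(`0.98`, so the averaging horizon stays a small fraction of the schedule,
as `0.999` is of a full-scale run; an averaging window as long as the
whole run would evaluate mostly pre-convergence weights).

## Known limitations

* No GPU path; the engine is tuned for a single CPU core at desk scale.
* EDF import/export and HDF5 containers are not provided; recordings and
  sample sets serialize as RDS with JSON metadata sidecars.
* Only the shallow-ConvNet backbone is implemented as a comparison point;
  the wider model zoo around the architecture is out of scope.
* Subject-independent transfer, GAN augmentation, and t-SNE feature maps
  are out of scope.
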