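# macnet

Four-class lower-limb motor-imagery EEG decoding in R: a shallow-ConvNet
backbone augmented with multidimensional attention ("MACNet"), the full
offline preprocessing chain, seeded training and cross-validated
evaluation, an experiment battery (ablations, channel reduction,
complexity audit, ERD topography), and a synthetic generator of
event-related-desynchronization (ERD) structured EEG so that the entire
pipeline runs, and is tested, without access to recording hardware or
restricted subject data.

## Who this is for

Researchers and students in EEG brain–computer interfaces who want a
self-contained, fully reproducible reference implementation of an
attention-enhanced ConvNet decoder for motor imagery — including every
unglamorous step (epoching, mastoid re-referencing, filtering,
sliding-window augmentation, trial-level cross-validation) that published
accuracy figures silently depend on.

## The model

Input samples are normalized 61-channel × 250-point windows (1 s at
250 Hz).  The network, per branch:

| stage | operation | output |
|---|---|---|
| temporal refining (branch I, II) | single-head self-attention over time tokens, `A = softmax(QKᵀ/√d)`, residual `X̃ = X + (AV)ᵀ` | 61 × 250 |
| temporal convolution | 40 filters (1, 25), valid | 40 × 61 × 226 |
| CBAM + skip (branch II) | channel gate `Mc = σ(MLP(avg) + MLP(max))`, spatial gate `Ms = σ(f⁷ˣ⁷[avg; max])`, `F + Ms ⊗ (Mc ⊗ F)` | 40 × 61 × 226 |
| spatial convolution | 40 filters (61, 1) | 40 × 1 × 226 |
| log-power head | affine-free batch norm → square → mean-pool (1, 75)/(1, 15) → dropout 0.3 → `log(max(x, 10⁻⁶))` | 40 × 1 × 11 |
| classifier | (1, 11) convolution → softmax over 4 classes | 4 |

Branch 0 (no attention) is the shallow-ConvNet baseline with 100,444
learnable parameters; the full branch II holds 111,908.  Training is Adam
with cosine annealing, cross-entropy loss, and a zero-debiased
exponential-moving-average shadow of all weights used for evaluation.
Forward, backward and the optimizer are implemented in single-precision
RcppArmadillo; every layer has a double-precision reference implementation
in R checked against independent loop oracles.

## Worked example

```r
library(macnet)

# one session of synthetic 64-channel, 1000 Hz MI-EEG: 24 balanced trials,
# mu rhythm over the sensorimotor strip with class-dependent ERD
spec <- sim_spec(trials_per_session = 24, snr = 25, erd_depth = 0.5,
                 seed = 11)
rec <- generate_recording(spec)
rec
#> <eeg_recording> 64 channels x 243000 samples @ 1000 Hz, 24 events

# epoch 0.5-5.5 s, drop EOG, re-reference to linked mastoids, 7-31 Hz
# Butterworth (order 5, zero-phase), decimate to 250 Hz, cut five
# nonoverlapping 1 s windows per trial, min-max normalize
samples <- preprocess_recording(rec)
samples
#> <sample_set> 120 samples x 61 channels x 250 points @ 250 Hz
#>   classes: S-ST=30, ST-S=30, walking=30, standing=30

# trial-level 3-fold cross-validation of the full model (desk-scale
# schedule: 50 epochs, step size scaled to the short run)
cfg <- macnet_config(branch = "II")
tc  <- train_config(lr = 1e-3, epochs = 50, batch_size = 4,
                    ema_decay = 0.98, seed = 1)
rep <- kfold_cv(samples, cfg, tc, k = 3)
rep
#> <eval_report> 3 fold(s), trial-level split
#>   accuracy 99.17% +/- 1.44, kappa 0.989

audit_complexity(cfg)$params_K
#> [1] 111.908
```

The accuracy line says the decoder recovered the planted class structure
from held-out *trials* (the five windows of a trial never straddle the
train/test boundary); `kappa` is the chance-corrected agreement, and
`audit_complexity()` confirms the 111.91 K learnable-parameter budget of
the full model.  `run_ablation()` repeats the CV per attention branch,
`psd_topography()` + `diff_map()` show the mu-band power drop over the
motor strip that drives the decoding.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/macnet.R simulate --seed 7 --trials 24 --out rec.rds
Rscript inst/cli/macnet.R preprocess --in rec.rds --out samples.rds
Rscript inst/cli/macnet.R complexity --branch II
```

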