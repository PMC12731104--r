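---
title: "Methods: hierarchical graph learning for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical graph learning for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator emulates, the numerical choices, and the places
where the design was genuinely open and a decision had to be made.

## The decoding problem

A motor-imagery (MI) trial is a short multichannel EEG segment recorded
while a subject imagines one of four movements (left hand, right hand,
feet, tongue). The discriminative signal is mostly *event-related
desynchronization* (ERD): a task-specific attenuation of the mu (8–12 Hz)
and beta (13–30 Hz) rhythms over the corresponding sensorimotor cortex.
Laterality conventions differ across texts; this package follows the
electrode–task map C3 ↔ left hand, C4 ↔ right hand, Fz ↔ feet,
CPz/Pz ↔ tongue throughout, including in the simulator — internal
consistency is what the decoder needs, not a stance on contralateral
organization. Volume conduction
spreads each cortical source over many electrodes, so channel-wise
features are both redundant and noisy; the model therefore works on
*graphs* over the electrodes at three granularities.

## The three branches

**Local.** Directed functional coupling is estimated with partial directed
coherence (PDC). Each trial is fit with a multivariate autoregressive
(MVAR) model `x_t = Σ_{r=1..p} A_r x_{t−r} + ε_t` by least squares; with
`Ā(f) = I − Σ_r A_r e^(−i2πfr/fs)` the PDC from source j to sink i is

```
PDC_ij(f) = |Ā_ij(f)| / sqrt(Σ_m |Ā_mj(f)|²)
```

normalized over the *source column*, so `Σ_i PDC_ij(f)² = 1` exactly and
every entry lies in [0, 1]. PDC is averaged over a 1 Hz grid spanning
8–30 Hz and over all training trials, the diagonal is zeroed, and the
result is symmetrically normalized, `Ǎ = D̃^(−1/2)(A + I)D̃^(−1/2)` with
`D̃` the row sums of `A + I`. Two temporal convolutions (kernels 1×85 and
1×30, each followed by batch norm, ReLU and a width-2 max-pool) extract
per-channel features; one graph convolution `Z = GeLU(Ǎ X W + b)` (the
K = 1 Chebyshev update) mixes them along the learned coupling structure.

**Partition.** The 22 electrodes are split into four overlapping
task-driven partitions, sizes (7, 10, 7, 10); electrodes C1, CP1, C2, CP2
belong to three partitions, FC1, FC2, Cz, CPz to two. Within a partition,
spatial adjacency is the Gaussian median distance (GMD):

```
w_ij = 1                 if d_ij = 0
       exp(−d_ij²/δ²)    if 0 < d_ij ≤ δ
       0                 if d_ij > δ
```

with δ the *median* pairwise electrode distance of the partition — a
robust bandwidth that makes the whole construction invariant to global
rescaling of the montage coordinates. The graph filter
`F = I − D_out^(−1) A_P` (random-walk Laplacian) is applied to the raw
signals; it annihilates constants (rows sum to 0), i.e. removes each
node's neighbourhood average — a graph-local common-mode reference that
counters volume-conduction smear. The prose around this operator calls it
smoothing; as printed it is the complement of a smoother (it *subtracts*
the neighbourhood average). It is implemented exactly as printed and the
tension is noted here once. Each partition then runs the temporal block
*without* pooling, and overlapping electrodes are fused by the arithmetic
mean of their per-partition feature vectors, yielding one feature vector
per distinct electrode in montage order.

**Global.** The local and (fused) partition features are concatenated per
node. The adjacency here is *dynamic*: recomputed on every forward pass as
the cosine similarity of the current node features, negatives clamped to
zero (config `abs` alternative) so that the degree normalization stays
well defined, diagonal pinned at 1, then self-looped symmetric
normalization. Two residual graph convolutions follow:

```
Z¹ = GeLU(Ǎ₁ Z_fuse W₁ + b₁)
Z² = GeLU(Ǎ₂ (Z_fuse + Z¹) W₂ + b₂) + Z_fuse
```

with Ǎ₁ built from `Z_fuse` and Ǎ₂ from `Z_fuse + Z¹` (a config flag
shares Ǎ₁ instead). Gradients flow *through* the dynamic adjacency; the
package's autodiff tape differentiates the row normalization, the Gram
product, the clamp and the symmetric normalization, and the
finite-difference acceptance test covers the complete path.

A flattened readout, two fully connected layers (ReLU + dropout between
them) and a softmax produce the four class probabilities; the loss is mean
cross-entropy.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band-pass | 0.5–40 | Hz | 6th-order Butterworth, zero phase; keeps mu+beta, kills drift and line noise |
| MVAR order `p` | 5 | lags | unspecified upstream; 5 lags at 250 Hz ≈ 20 ms of history, standard for EEG PDC; overridable |
| PDC band | 8–30 | Hz | mu+beta, where ERD lives; 0.5–40 available |
| kernels | 85, 30 | samples | 0.34 s and 0.12 s at 250 Hz: macroscopic then local temporal structure |
| conv channels | 8, 16 | filters | sized (with the rest) to land the ~0.5 M parameter budget |
| `gcn_hidden` | 64 | features | local graph-embedding width |
| `partition_summary` | mean over time | — | collapses fused partition features to one value per conv channel before the global module (see below) |
| dropout / lr / batch / weight decay / L2 | 0.5 / 0.001 / 64 / 0.01 / 0.069 | — | the published training protocol; the L2 penalty applies to graph-layer weights only |

At these defaults the model has 481,044 trainable parameters
(regression-tested), close to the published 0.513 M budget.

### Why `partition_summary` exists

The printed architecture feeds the partition branch's *unpooled* flattened
features (conv channels × ≈887 time points per node at 1000 samples)
straight into the global module, whose residual form forces both global
weight matrices to be square in that width — about 1.6 × 10⁹ parameters,
four orders of magnitude above the published budget. Something unstated
must reduce that width; this package's choice is the least parametric one:
a temporal mean per conv channel after fusion (ReLU activations averaged
over time ≈ mean rectified amplitude, a band-power-like statistic that is
exactly the right summary for ERD). Setting `partition_summary = "none"`
restores the literal wiring for small inputs.

### Other open points, decided

* **Dropout placement**: between the two FC layers only. Dropout after the
  output layer would randomize the logits themselves.
* **"Global only" ablation**: with both upstream branches removed, the
  global module consumes node features from a plain pooled temporal block
  (summarized like the partition features). The source never specifies
  this configuration's input.
* **Eq.-level ambiguities**: the PDC denominator is normalized over the
  source column (the printed index is treated as a typo — it contradicts
  the stated j→i semantics and the (0,1) property); the PDC adjacency is
  kept *directed* with row-degree normalization (a `symmetrize` flag
  averages with the transpose first); δ is computed once from montage
  geometry, not per trial (distances are static; "per trial" is read as
  applying the same filter to every trial).
* **Reported epoch**: evaluation uses the final epoch's parameters, not
  the best epoch.
* **Test accuracy protocol**: cross-session (train on one simulated
  session, test on an independently seeded one).

## The synthetic-data generator

Real MI benchmarks cannot ship with the package, so every end-to-end claim
rests on `simulate_session()`. Its stated world: 6 runs × 48 trials
(12 per class, shuffled within run) of 4 s at 250 Hz on the 22-channel
montage. Per channel and trial the signal is 1/f^a background noise
(a = 1, spectral shaping of white noise) plus an snr-scaled band-limited
mu rhythm whose amplitude is `1 − depth · exp(−d²/δ²)` with d the distance
to the class's nearest focal electrode — ERD as attenuation, spread to
neighbours with the same Gaussian/median-distance law the model assumes.
Directed coupling edges add a lagged scaled copy of a source channel to a
target, giving PDC a known ground truth.

What it does *not* emulate: volume conduction through a head model
(attenuation is spatially smooth, but there is no leadfield mixing),
artifacts (blinks, EMG), non-stationarity across runs, inter-subject
variability, beta-band ERD. A green learning test therefore establishes
that the implementation can extract planted spatio-spectral structure from
realistically noisy signals — not that it reaches any particular accuracy
on real recordings. Desk-scale tests run at 128 Hz × 2 s with reduced
widths purely for CPU budget; the generator's structure is unchanged.

## Numerical choices

* **Band-pass**: implemented spectrally — each trace is reflection-padded
  and multiplied in the frequency domain by the *squared* analog
  Butterworth band-pass magnitude, which is exactly the zero-phase
  magnitude of forward–backward filtering without hand-rolled IIR state
  arithmetic. Verified against the analytic response (unit gain in band,
  |H(60 Hz)|² ≈ 0.008, DC → 0).
* **MVAR**: per-trial least squares via QR; rank deficiency and too-short
  trials raise structured errors. PDC columns with vanishing norm raise a
  numeric error rather than returning NaN.
* **Clamp subgradients**: cosine values at the clamp boundaries get
  gradient 0; the diagonal is constant 1 with gradient 0 (its input
  derivative is identically zero anyway).
* **Batch norm**: batch statistics in training (population variance in the
  normalizer, unbiased in the running estimate, momentum 0.1), running
  statistics in evaluation.
* **Softmax/cross-entropy**: fused with the max-subtraction trick; the
  public API reports probabilities.
* **Determinism**: all randomness flows through R's RNG; a fixed seed
  reproduces simulation, initialization and training bit-for-bit on one
  CPU.
* **Gradient checks**: finite differences agree with the tape to < 1e−4
  relative at ε = 1e−6 on a tiny model. Larger ε inflates the discrepancy
  through ReLU/max-pool kink crossings — nondifferentiability, not error.

## Known limitations

* No GDF/EDF/BrainVision importers: the canonical container plus TSV
  adapters keep the core dependency-free; adapters can be added without
  touching the pipeline.
* The 32-channel laboratory layout's partition membership is not
  hard-coded (it is published only as a figure); users supply a scheme
  file for other montages.
* Training is pure R + BLAS: fine at package scale (minutes), roughly two
  orders of magnitude slower than a GPU framework at full benchmark scale
  with 100 repetitions.
* Statistical thresholding of PDC, time-varying connectivity, learned
  adjacency and attention variants are out of scope.
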