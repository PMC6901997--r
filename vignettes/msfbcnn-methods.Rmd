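---
title: "Decoding motor imagery with a multiscale filter-bank CNN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with a multiscale filter-bank CNN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Imagining a limb movement suppresses (event-related desynchronization, ERD)
or enhances (ERS) the sensorimotor mu (8–12 Hz) and beta (16–26 Hz) rhythms
over the cortical representation of that limb. A motor-imagery
brain–computer interface must detect, from a single epoch of multichannel
EEG (a `C` channels × `T` samples matrix, microvolts), which limb the user
imagined. The classical solution — band-pass filter banks, common spatial
patterns (CSP), log-variance features, and a linear classifier — is here
folded into one end-to-end convolutional network whose layers mirror those
stages, so every parameter of the classical pipeline becomes learnable.

## The network

The architecture has three tagged subnetworks:

1. **Feature extraction.** Four parallel temporal convolutions with kernel
   lengths 64, 40, 26 and 16 samples (at 250 Hz: ~256 ms down to 64 ms) and
   `F_T` filters each act as a learned multiscale filter bank; "same"
   padding keeps `T`. Their concatenation (`4 F_T` maps) is
   batch-normalized and passed to a spatial convolution of kernel `(1, C)`
   with `F_S` filters — the learned analogue of CSP — and a second batch
   norm. Convolutions carry no bias: the following batch norm would absorb
   it.
2. **Feature reduction.** Squaring, average pooling over 75-sample windows
   with stride 15 ("valid"), and a logarithm turn each spatially filtered
   signal into its windowed log band power, the same statistic as the
   classical log-variance feature; dropout (`p = 0.5`) regularizes it. This
   stage has no trainable parameters.
3. **Classification.** A convolution whose kernel spans the whole pooled
   axis (`L = floor((T - 75)/15) + 1`, so `L = 71` at `T = 1125`) produces
   `N_C` class scores with `F_S · L · N_C` weights and an `N_C` bias;
   log-softmax maps the scores to log-probabilities, and training minimizes
   the categorical cross-entropy `-Σ_i p_i log q_i` in the log domain.

`compute_layer_shapes()` is the executable form of this arithmetic; the
test suite checks every built model against it. Two printed-table
conventions deserve note, since the reference description of this
architecture is ambiguous on both: the pooled length is often abbreviated
`T//15`, but valid pooling with window 75 and stride 15 gives `L = 71` at
`T = 1125`, which is what the implementation uses and what the classifier
kernel is sized to; and the first batch norm normalizes all `4 F_T`
concatenated maps, hence carries `2·(4 F_T)` parameters — the standard
per-channel form.

The ratio `D = F_T / F_S` may be given instead of `F_S`, mirroring the
usual two-stage hyperparameter search in which `D` is enumerated first and
`F_S` adjusted under fixed `D`.

### Numerical choices

Batch norm uses ε = 1e-5 and running-statistics momentum 0.1 (current batch
weight), with unbiased batch variances feeding the running estimates. The
pooled power is floored at 1e-12 before the log so an all-zero input yields
finite features instead of `-Inf`; gradients are zeroed where the floor
engages. "Same" padding with even kernels puts the extra zero on the right
(`pad_left = floor((k-1)/2)`). Dropout is inverted (activations scaled by
`1/(1-p)` during training) so evaluation needs no rescaling. All
randomness — initialization, shuffling, dropout masks, simulator draws —
runs through R's RNG, so a single seed pins a whole run bit-for-bit.

### Initialization

Two schemes are provided. The `"paper"` scheme draws every convolution
weight from the standard normal (zero mean, unit variance) with batch-norm
scales 1 — the recipe as literally described for this architecture. Because
no batch norm follows the classifier convolution, unit-variance classifier
weights produce logits with standard deviation of order `sqrt(F_S · L)`:
the softmax saturates, the initial loss is tens of nats, and Adam spends
many epochs rescaling before accuracy moves (in our simulations the scheme
is still near chance after 25 epochs). The `"scaled"` scheme
(`sd = 1/sqrt(fan_in)`) removes the saturation and learns from the first
epoch. `"paper"` remains the default to honor the recipe; every packaged
experiment and the acceptance suite use `"scaled"`, and we read the
original description as a simplification of whatever the framework it ran
on actually did.

## Preprocessing

The chain is crop → resample → band-pass → standardize, each step
optional and reorderable via `preprocess(steps =)`; this order does the
expensive filtering on the shortest signals and standardizes last so the
network sees unit-scale input.

* **Crop**: half-open window `[t0, t1)`, so 0–4.5 s at 250 Hz is exactly
  1125 samples.
* **Resample**: polyphase rational resampling with anti-alias filtering
  (`signal::resample`); only downsampling is supported (500 → 250 Hz being
  the practical case).
* **Band-pass**: 4th-order Butterworth prototype, 4–38 Hz, applied
  forward–backward (zero phase) with odd-reflection padding to suppress
  edge transients. The pass band keeps mu and beta and rejects drift and
  50/60 Hz line noise.
* **Exponential moving standardization**: per trial and channel, running
  mean `m_t = d·m_{t-1} + (1-d)·x_t` and running variance
  `v_t = d·v_{t-1} + (1-d)(x_t - m_t)²` with decay `d = 0.999`, output
  `(x_t - m_t)/sqrt(max(v_t, 1e-4))`. The recursions are seeded with the
  mean and variance of the first 100 samples, so early samples are
  standardized by a defined scale instead of the variance floor; the
  transform is causal and scale-invariant except for degenerate
  near-constant signals. Statistics restart at every epoch boundary
  (epoched data carry no continuity guarantee); running them across a
  continuous recording is an extension point, not a config switch we
  currently expose.

The decay and floor are conventional values from the EEG deep-learning
tooling this recipe originates from; both are exposed in
`preproc_config()`.

## Training and transfer

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) minimizes the cross-entropy with
learning rate 1e-3, batch size 64 and L2 weight decay 1e-7 — we read the
"decay weight" of the recipe as an L2 coefficient in the optimizer, the
standard meaning in this literature. There is no early stopping: training
runs a fixed number of epochs and returns the checkpoint with the best
validation accuracy (earliest epoch on ties), which keeps runs
reproducible.

Cross-subject transfer proceeds in two stages. `pretrain_pooled()`
concatenates all source subjects and trains a "coarse" model (10% internal
stratified validation split). `fine_tune()` then continues training on the
target subject's calibration trials, mixed with an equal number of
seeded-randomly drawn source trials (`mix_ratio = 1` by default; the
original recipe says the individual data are "mixed with a randomly
selected open dataset" without a proportion), with per-subnetwork learning
rates of 1/27 (feature extraction), 1/9 (feature reduction — a no-op here
since that stage has no parameters, but the slot is kept for variant
architectures), and 1/3 (classifier) of the base rate. The mixing pool is
the other subjects of the same family; validation data, when supplied,
only monitor and select the checkpoint, they are never trained on.
`small_sample_protocol()` wraps this into the calibration-curve
experiment: for each requested size `n` (10, 20, 50, 100 by default) and
seed, draw `n` stratified target trials, fine-tune a fresh copy of the
coarse model, and score on the target's test split.

## The simulator

`generate_dataset()` emulates exactly the statistical structure the
network exploits: every channel carries a mu and a beta oscillator
(sinusoids with per-trial frequency drawn uniformly in-band and
per-channel random phase) on top of 1/f background noise (white spectra
shaped in the frequency domain, exponent 1 by default); within the event
window (0.5–3.5 s by default, mimicking a cue at 0.5 s) the class's
channel group is multiplied by its gains — 0.4 (mu) and 0.6 (beta) by
default, i.e. ERD. The default montage is 22 channels with the left-hand
class modulating the first half and the right-hand class the second,
6 µV mu, 3 µV beta, 2 µV RMS noise: a clearly detectable single-trial
contrast, as in a good MI session. Sinusoidal oscillators were chosen over
band-filtered noise because their band power has a closed form (A²/2),
which the test oracles use.

`generate_subject_family()` adds inter-subject variability: each subject
draws an amplitude factor (log-uniform within [1/2, 2] by default), a band
shift (±1 Hz), a circular rotation of the modulated channel groups (±4
channels), and a noise factor ([1/1.5, 1.5]). Rotation is the component
that genuinely hurts zero-shot transfer — it moves the discriminative
spatial pattern, as electrode placement and functional anatomy differences
do across real subjects.

What the simulator does *not* model: volume conduction and realistic
spatial mixing, non-stationarity within a session, eye/muscle artifacts,
and 50 Hz line noise. Passing tests on simulated data therefore
demonstrate that the implementation learns and transfers on data with the
assumed ERD/ERS structure — not that it attains any particular accuracy on
real recordings.

## Simulation-study sizes

The packaged experiments (test suite and `scripts/acceptance.R`) use sizes
chosen for a single-CPU run while keeping the study conditions intact:

* *Intra-subject learning*: the default 2-class dataset (22 channels,
  1125 samples after preprocessing), 400/100/100 train/valid/test trials,
  a compact `F_T = F_S = 4` network (the 2-class simulated contrast does
  not need the full `F_T = 40` bank), batch 32, 15 epochs, `"scaled"`
  init. This reaches ≥ 0.9 test accuracy with a comfortable margin
  (≈ 0.95 in our runs).
* *Transfer*: a 4-subject family at 12 channels × 3 s with weaker effect
  sizes (4 µV mu, 3 µV RMS noise, gains 0.55/0.7) so that neither
  within-subject nor zero-shot accuracy saturates; pretraining on three
  subjects, fine-tuning on the fourth over calibration sizes
  {10, 20, 50, 100} × 5 seeds.

## Known limitations

* The `"paper"` initialization is faithful but practically untrainable
  within small epoch budgets (see above); experiments use `"scaled"`.
* Batch norm uses batch statistics during training only; very small
  fine-tuning batches (n = 10 with mixing gives 20 trials) make those
  statistics noisy — one reason the calibration curve flattens at small n.
* The EDF/GDF import path for real competition recordings is an extension
  point: the container format and `eeg_epochs()` are the interface, and
  any epoching front end (e.g. MNE in Python) can write it.
* Training is single-threaded apart from BLAS; the implementation favors
  reproducibility over parallel speed.
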