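---
title: "Methods: a binarized-network pipeline for sEMG gesture recognition"
author: "emgbnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a binarized-network pipeline for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of muscle
fibers through skin electrodes. A single dry-electrode channel on the wrist,
sampled at 1000 Hz, carries enough information to distinguish dynamic hand
gestures — rest–motion–rest sequences of finger and wrist movement — because
different gestures recruit muscle groups with different timing and different
spectral emphasis within the 10–500 Hz sEMG band.

`emgbnn` implements the full classification pipeline for this setting,
engineered for the memory and arithmetic constraints of embedded hardware:

1. a 2.112 s trial of 2112 10-bit ADC codes is converted into a 32×32
   time–frequency magnitude image (STFT spectrogram with powerline-harmonic
   bins removed);
2. a binarized convolutional neural network (BNN) — weights and activations
   in {−1, +1} — classifies the image into one of nine gesture classes;
3. inference is *bit-exact* with a hardware datapath: multiplications are
   XNORs, sums are popcounts, max-pooling is a logical OR, and batch
   normalization plus sign activation is a single integer comparison per
   channel.

Because no public recording set accompanies this task, the package ships a
synthetic trial generator that defines the study conditions for every test.

## Synthetic sEMG generator

Each trial is built in the continuous domain and then quantized:

* **Background activity**: Gaussian noise band-limited to 10–500 Hz with a
  4th-order zero-phase Butterworth band-pass (`signal::butter` +
  `signal::filtfilt`), scaled to a low resting amplitude (default 0.05
  relative units).
* **Bursts**: each gesture template holds one or two bursts. A burst is
  band-limited Gaussian noise in its own sub-band, shaped by a Hann envelope
  over `[onset, onset + duration]`, with unit relative amplitude. The
  interference-pattern character of real sEMG is stochastic, so filtered
  noise is the right first-order model; what distinguishes classes is the
  *time–frequency support*, which is exactly what the spectrogram classifier
  sees.
* **Hum**: sinusoids at 60 Hz and its harmonics up to 480 Hz, with per-trial
  random phases and fixed code-unit amplitudes (default 10 codes at the
  fundamental, decaying with harmonic order).
* **ADC**: unipolar 10-bit converter — offset to midscale 512, saturating
  clip to [0, 1023], round to integer. Amplitude calibration
  (`gain_codes = 110`) places burst peaks around half of the ADC headroom,
  loud but unclipped, a realistic operating point for a conditioned sEMG
  front end.

The nine default templates differ in burst count (1 vs 2), onset
(early/late), duration (0.45 s vs 1.2 s), and band emphasis (low 20–120 Hz,
mid 120–250 Hz, high 250–450 Hz, broadband). These values are the package's
own choice: they make classes learnable but not separable by any single
feature, which is what the pipeline-level tests need.

What the generator does **not** emulate: motor-unit action-potential shapes,
electrode-skin impedance drift, sweat/fatigue/placement covariates across
sessions, or inter-subject variability. Tests passing on synthetic data
therefore demonstrate that the pipeline is implemented correctly and that the
architecture can learn spectro-temporal structure at this SNR — not that any
particular accuracy transfers to real recordings.

Determinism: every trial's seed derives from
`trial_seed(master_seed, class_id, replicate)`, a fixed 32-bit congruential
mix, so datasets are reproducible as a whole and trial by trial.

## Preprocessing

```{r}
library(emgbnn)
tr <- generate_trial(default_gesture_templates()[[3]], seed = 42)
s  <- make_spectrogram(tr)   # 32 x 32, frequency x time
```

* **Framing**: 128-sample frames, hop 64 (50% overlap);
  `(2112 − 128)/64 + 1 = 32` frames, the last ending exactly on sample 2112.
* **Window**: symmetric Hamming, `w[k] = 0.54 − 0.46 cos(2πk/127)`. The
  symmetric (N−1) form is the classic definition; the choice is immaterial
  downstream because the classifier never compares across window variants.
* **Transform**: 128-point FFT (`stats::fft`); the input is real, so only
  bins 0–63 are kept. The implementation is checked against an O(N²) DFT
  oracle to 1e−9 relative tolerance, and windowed energy satisfies Parseval
  to 1e−6.
* **Magnitude**: the default is the hardware-friendly L1 form
  `|Re| + |Im|`, which over-estimates the modulus by a factor in
  [1, √2] (worst case on the diagonal). The exact modulus is available via
  `stft_config(magnitude = "exact")` for comparison studies.
* **Harmonic removal**: powerline hum contaminates DC and every multiple of
  60 Hz up to 480 Hz. The filter drops a group of adjacent bins per center —
  sizes 4,4,3,3,4,3,3,4,4 by default, 32 bins in total — leaving 32 of 64
  bins and fixing the image height at 32. With a 7.8125 Hz bin width the
  harmonic centers fall *between* bins, so each group spans the bins the hum
  leaks into; every group contains the bin nearest its center. The exact
  default indices are a package choice (any table satisfying the size,
  adjacency and nearest-bin constraints is accepted via
  `harmonic_filter_spec()`).
* **No mean subtraction** before the transform: DC and its neighbors are in
  the removed set anyway.

A hardware-emulation mode (`hw_emulation = TRUE`) replaces the float window
and twiddle factors with 8-bit and 10-bit lookup tables. It models table
quantization only — not fixed-point butterfly scaling, which the hardware's
staged FFT would additionally introduce — and is excluded from the package's
acceptance checks for that reason.

## The binarized network

The selected architecture is five convolution layers (16/32/64/128/256
filters) and three fully connected layers (256/512/9). Two geometric facts
are *derived*, not assumed, and asserted at construction time:

* the kernel size must be 3×3, because the published weight total 789,648
  satisfies `43,536·k² + 397,824` only at `k = 3`;
* there are 2×2 pools after conv 2–5 (none after conv 1), because the first
  FC fan-in 1024 equals `2·2·256` only after four halvings of a 32×32 input.

Parameter accounting: 391,824 conv weights + 397,824 FC weights = 789,648
one-bit weights; 496 conv + 768 FC thresholds = 1264; 790,912 parameters in
total. The final 9-node layer carries **no** thresholds — the threshold count
decomposes as 496 + (256 + 512) only if the output layer is excluded — and
classification is the argmax of its raw integer scores, ties broken toward
the lowest class index.

Engine semantics, all covered by oracle tests:

* **Encoding**: stored bit `b ∈ {0,1}` means value `2b − 1`. The ±1 dot
  product of packed vectors is `2·popcount(XNOR) − n`.
* **Padding**: "zero padding" is literal — a padded tap contributes 0,
  neither +1 nor −1. The packed engine excludes padded taps from the
  popcount; an all-(+1) 3×3 input convolved with an all-(+1) 3×3 kernel
  yields 9/6/4 at center/edge/corner, the standard CNN semantics.
* **Thresholds**: channel fires (+1) iff `acc ≥ θ` (`ge`), or `acc < θ`
  (`lt`, the negative-BN-scale case). The tie `acc = θ → +1` mirrors
  `sign(0) → +1` and must be fixed once for bit-exactness.
* **OR pooling**: on binary maps the 2×2 max is the OR of the stored bits
  (verified exhaustively on all 16 blocks).
* **First layer**: default `binary_input` mode binarizes the spectrogram
  against per-frequency-bin thresholds (training-set medians, stored with
  the model) so the whole datapath is XNOR; `integer_input` mode feeds
  multi-bit pixels into a ±1-weight first convolution instead. Both are
  implemented because the hardware description leaves this ambiguous.
* **Packing**: weights concatenate in layer order, each tensor in its array
  flatten order, LSB-first into little-endian 128-bit words:
  `ceiling(789,648 / 128) = 6170` words with 112 zero slack bits.

The packed engine is cross-checked, bit for bit, against a dense ±1
arithmetic reference network on randomized architectures and inputs,
including channel counts that cross the 64-bit word boundary.

## Training and threshold folding

There is no deep-learning framework in the package's dependency set; the
training loop is implemented directly (R with compiled im2col/col2im
helpers, BLAS matrix products for the convolutions):

* forward passes binarize latent weights (`sign`, with `sign(0) → +1`) and
  activations end to end — in `binary_input` mode the input itself is
  binarized with the same frozen thresholds used at inference, so training
  matches deployment;
* gradients pass through the sign via the straight-through estimator, gated
  to `|pre-activation| ≤ 1`; latent weights are clipped to [−1, 1] after
  each Adam step (standard binarized-training practice; the clipping window
  and latent representation are training-side choices that leave no trace in
  the exported model);
* batch normalization (ε = 1e−5) is trained in float; running statistics
  (momentum 0.1) are what gets folded at export;
* the default recipe is Adam, cross-entropy, 200 epochs, batch 128, learning
  rate 0.01/0.005/0.0005/0.00005/0.000005 stepping at epochs 0/40/80/120/160,
  80/20 stratified split (split seed separated from the init seed).

**Folding is exact.** With `s = √(var + ε)` and `t = μ − β·s/γ`:
for `γ > 0` the channel fires iff `x ≥ t`, i.e. iff `x ≥ ⌈t⌉` for integer
accumulators (direction `ge`); for `γ < 0` it fires iff `x ≤ t`, i.e. iff
`x < ⌊t⌋ + 1` (direction `lt`); `γ = 0` makes the channel constant at
`sign(β)`. A property test sweeps every integer accumulator in [−1200, 1200]
for hundreds of random BN draws and requires equality with `sign(BN(x))`
everywhere. Quantization to the 14-bit range [−8192, 8191] is lossless for
this architecture: every layer's accumulator range (max fan-in 1152 for conv,
1024 for FC) lies strictly inside it, and any threshold outside its layer's
achievable range is converted to a constant channel rather than clamped.

Model files are a directory: `weights.bin` (the packed word stream) plus
`manifest.json` (architecture, thresholds, input thresholds, counts, MD5 of
the stream). Serialization is covered by a train → fold → write → read →
forward bit-exactness test.

## Memory accounting conventions

The report mirrors the packed system's memory map: two 128-bit × 1024
buffers (spectrogram/feature-map ping-pong), the 8-bit × 128 window table,
the 10-bit × 64 twiddle table, the 128-bit × 6170 weight stream, and the
14-bit × 1264 threshold table — 1,071,264 bits in total. Two conventions are
forced by the published derived figures and adopted here: KB means 1000
bytes (789,648 bits = 98,706 bytes = 98.706 KB), and the full-precision
baseline counts weights only at 64 bits each (6,317.184 KB), giving a 98.4%
reduction. The weight-memory row is `width × depth` = 789,760 bits — the
112 slack bits of the last word are part of the memory, not of the model.

## Problem sizes used by the test suite

The suite trains real networks, scaled to desk size: module-level training
tests use an 8/8-filter, 16-node network on 72 trials for six epochs;
the pipeline-level learnability check trains the full selected architecture
on 1800 trials (200 per class, master seed 11) for five epochs at batch 64
and requires ≥ 90% accuracy of the *folded, packed* model on the held-out
20%. Five epochs suffice because the synthetic classes are designed to be
well separated; the published 200-epoch recipe remains the default for real
use. Engine-vs-oracle checks run on small random architectures where the
dense reference is cheap.

## Known limitations

* The synthetic generator's realism limits are listed above; no claim is
  made about accuracy on real recordings.
* `hw_emulation` models table quantization only, not staged fixed-point FFT
  arithmetic.
* The exact harmonic-removal bin indices and the hardware's first-layer
  input handling are not recoverable from the published description; both
  are configurable, with defaults chosen to satisfy every stated constraint.
* Training is CPU-bound and single-threaded apart from BLAS; it is meant
  for desk-scale experiments, not GPU-scale sweeps.
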