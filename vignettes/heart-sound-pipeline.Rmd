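---
title: "Classifying heart sounds with a customized 1-D CNN"
author: "pcgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying heart sounds with a customized 1-D CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgnet)
```

## The problem

Auscultation — listening to the heart at the chest wall — is the first
screening step for congenital heart disease, but its accuracy depends
strongly on clinician experience. A phonocardiogram (PCG) records the same
acoustic signal digitally: the S1 and S2 valve-closure transients dominate a
normal recording below roughly 200 Hz, while murmurs (turbulent flow between
the transients) spread energy into higher bands, typically 200–400 Hz. This
package implements an end-to-end pipeline that classifies PCG recordings as
*normal* or *abnormal* with a one-dimensional convolutional network operating
directly on the filtered waveform, so no hand-crafted features are needed.

## The pipeline

A recording passes through five stages:

1. **Band-pass filtering.** A zero-phase Butterworth band-pass removes
   low-frequency rumble and high-frequency noise. Two presets ship:
   `physio` (20–500 Hz, prototype order 4; the default) and `audacity`
   (60–650 Hz, order 8, equivalent to a 48 dB/octave roll-off). The filter
   is applied forward and backward (`filtfilt` with odd-reflection padding),
   which cancels phase distortion so S1/S2 timing is untouched; the price is
   that the effective amplitude response is the square of the single-pass
   response (−6 dB rather than −3 dB at the edges). "Order" here counts the
   analogue prototype poles; the digital band-pass has twice as many.

2. **Resampling to the canonical 2000 Hz.** All heart-sound content of
   interest lies below 800 Hz, so 2000 Hz is comfortably above Nyquist.
   Resampling is polyphase/band-limited (`signal::resample`) with the
   rational rate ratio recovered by continued fractions; output length is
   `round(n * target_fs / fs)`, so duration is preserved to one sample.

3. **Peak normalization and segmentation.** Peak (not z-score) scaling keeps
   padded zeros exactly zero. Recordings are cut into 4-s windows (8000
   samples at 2000 Hz; an 8-s / 16,000-sample variant is a config switch),
   disjoint by default, and a trailing partial window is *wrap-padded* —
   repeated cyclically — because cardiac cycles are periodic, so a wrapped
   window still looks like heart sound. `overlap_frac` enables overlapping
   windows (e.g. 0.5) when more training segments are wanted.

4. **Pitch-shift augmentation.** Class imbalance is repaired by
   `balance_classes()`: minority-class segments are duplicated with their
   spectrum scaled by a factor drawn from a seeded pool (default
   `800/650` and its inverse, i.e. the shift that widens 60–650 Hz content
   to 60–800 Hz). The operator resamples by `1/factor` and wrap-pads back
   to length, so duration and label are preserved exactly while every
   narrowband component moves from `f` to `f * factor`. An aliasing guard
   rejects factors that would push the assumed content ceiling past
   Nyquist. Augmentation is applied **only to the training partition** —
   augmenting before the split would leak near-copies of test segments into
   training.

5. **Grouped, stratified, sequential splitting.** `split_dataset()` fixes
   the test size first (`round(0.15 N)`) and then the validation size from
   the remainder (`round(0.15 (N − n_test))`). This *sequential* rounding is
   the package default because a nominal 70/15/15 split of 15,231 segments
   under it yields exactly 11,004 / 1,942 / 2,285 — whereas simultaneous
   rounding gives a 2,285/2,284 tie and a smaller training set. Splitting is
   stratified by class (largest-remainder apportionment, per-part class
   ratios within one segment of global) and grouped by `source_id`, so
   segments of one recording never straddle partitions. With multi-segment
   recordings the grouped constraint can move a part's size by up to one
   group from its target; with one segment per source the sizes are exact.

## The network

`model_config()` defaults to six blocks of

    conv1d(kernel 3, same padding) → batch norm → ReLU → max-pool(2) → dropout(0.25)

with filter counts (64, 128, 128, 64, 32, 16), followed by
`flatten → dense(128) → ReLU → dropout(0.5) → head`. Same-padding
convolutions leave length control entirely to pooling, so the time length
after block $l$ is exactly `input_len / 2^l`, and `input_len` must be
divisible by $2^6$; a 4-s segment gives 8000 → 125 time steps → a flattened
feature of 125 × 16 = 2000, and an 8-s segment gives 16,000 → 250 × 16 =
4000. Two heads are available and config-selectable: a two-way softmax
(default, paired naturally with categorical cross-entropy) and a single
sigmoid unit emitting P(abnormal); both appear in practice and they are
mathematically equivalent for two classes. The filter schedule widens from
64 to 128 and then tapers through 64, 32, 16 — wide layers where the time
axis is long and feature extraction happens, narrow ones near the
classifier — with dropout 0.25 in the conv blocks and 0.5 at the dense
layer. Batch norm precedes ReLU. Weights are initialized from a seeded
uniform fan-in scheme.

The compute kernels (convolution as shifted-view GEMMs, batch-norm,
pooling, dropout, the full backward pass) are written in C++ with
RcppArmadillo in single precision; the backward pass is verified against
finite differences in the test suite at a small configuration. Denormal
floats are flushed to zero inside the kernels (they sit ~250 dB below
signal level and stall the FPU otherwise).

## Training and evaluation

`train_model()` runs mini-batch Adam (defaults: learning rate $10^{-3}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, batch 32,
30 epochs) on the binary cross-entropy with predictions clipped to
$[10^{-7}, 1 - 10^{-7}]$. The training history records per-epoch training
loss/accuracy (training mode) and validation loss/accuracy (inference
mode); optional early stopping returns the best-validation-loss weights.
Training is bit-reproducible from the config seed: shuffling draws from R's
RNG and the dropout masks from a per-batch xorshift stream seeded by it.

One numerical choice deserves a note. Batch-norm running statistics are
conventionally tracked as an exponential moving average (momentum 0.9).
At desk scale a training run may involve only a few dozen optimizer steps,
and the moving average then lags the fast-moving batch statistics badly:
the network ranks held-out segments almost perfectly (AUC near 1) while
inference-mode probabilities sit on the wrong side of 0.5. We therefore
**re-estimate** the running statistics after each epoch with a
dropout-free pass over (up to 128 of) the training segments, setting each
layer's running mean/variance to the average batch statistic. Each segment
contributes one observation per channel per time step, so 128 segments are
thousands of observations per channel even in the deepest block.

Evaluation computes the confusion matrix with **abnormal as the positive
class**, accuracy, precision, recall (sensitivity), F1 and specificity —
ratios with zero denominators are reported as missing-with-reason, never
silently zero — plus the ROC curve swept over every distinct score (ties
grouped) and its trapezoidal AUC. The trapezoidal AUC is checked against
the Mann–Whitney pair statistic (wins + half-ties over all
positive–negative pairs) and against pROC in the tests; the hard-label
threshold is 0.5, the ROC itself is threshold-free.

## The synthetic heart-sound generator

No clinical recordings ship with the package, so `generate_pcg()` simulates
the statistical structure the pipeline assumes:

* a per-recording heart rate drawn from 70–140 bpm (pediatric range) and
  per-recording S1/S2 tone frequencies from 60–120 Hz and 80–160 Hz;
* cardiac cycles at the implied period with ±5 % jitter on spacing and
  amplitudes, the cycle count fixed at `round(duration * hr / 60)` with
  jittered spacings rescaled to fill the recording exactly;
* S1 and S2 as Gaussian-windowed tone bursts (70 ms and 60 ms), S2 at 35 %
  of the cycle after S1;
* white background noise at −30 dB relative to the unit S1 peak;
* for the **abnormal** class, band-passed (250–350 Hz) noise gated over
  systole — the window between S1 and S2 — at a default 6 dB above the
  noise floor.

Recordings default to 10 s at 2000 Hz, and a dataset of 400 + 400
recordings mirrors a realistic balanced pediatric collection. Every
waveform is fully determined by a seed, and per-recording seeds are derived
from the master seed so any single file is regenerable in isolation.

The generator reproduces what matters to the *pipeline*: dominant
low-frequency transients, a murmur-band energy excess in the abnormal
class (monotone in the SNR knob), periodicity that justifies wrap padding,
and realistic durations. It does **not** model pathology-specific murmur
morphology (crescendo–decrescendo shapes, clicks, split S2), sensor or
contact artifacts, crying, or inter-patient variability beyond the jitter
above. Passing the end-to-end test therefore shows the pipeline can learn
a genuine spectral-timing cue from raw audio at realistic SNR — not that
it reaches any particular accuracy on clinical data.

## Desk-scale study sizes

The end-to-end acceptance study runs the default pipeline (murmur SNR 6 dB,
default architecture and optimizer) at 50 + 50 recordings and 10 epochs,
five seeds, requiring held-out accuracy ≥ 0.95 and AUC ≥ 0.98 in at least
four of five replicates plus a falling training loss (first-3 vs last-3
epoch medians). These sizes are the package's chosen desk scale: one
replicate trains on roughly 210 four-second segments in a few minutes on a
single core, which keeps the whole suite comfortably runnable while leaving
the task non-trivial (≈ 70 optimizer steps from random initialization).
`run_experiment()` exposes the same study at any size.

## Known limitations

* The CNN kernels are single-precision and single-threaded; training at
  clinical-archive scale (tens of thousands of segments) would want a GPU
  framework instead.
* `read_wav()` covers PCM 8/16/24/32-bit and IEEE float RIFF files — the
  dialects stethoscope exports actually produce — not the full WAV zoo
  (no ADPCM, no WAVE_FORMAT_EXTENSIBLE channel masks beyond the embedded
  format code).
* Grouped splitting with very uneven recordings can deviate from the exact
  sequential sizes by up to one recording per class.
* The two published passbands (20–500 Hz and 60–650 Hz) are both available;
  whether the original workflow cascaded them is unknowable from the
  source material, so the pipeline applies exactly one.
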