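# pcgnet

Binary classification of heart sounds — normal vs. abnormal — from raw
phonocardiogram (PCG) audio, with a customized one-dimensional convolutional
neural network and everything around it: WAV input, Butterworth band-pass
filtering, resampling, fixed-length segmentation, pitch-shift augmentation,
grouped stratified dataset splitting, Adam training, and full evaluation
(confusion matrix, accuracy/precision/recall/F1/specificity, ROC/AUC). A
synthetic heart-sound simulator makes the whole pipeline reproducible and
testable without clinical recordings.

The intended users are biomedical-signal researchers and engineers
prototyping automated auscultation: screening for congenital heart disease
from stethoscope audio, where murmurs (turbulent flow between the S1 and S2
valve sounds) add energy in roughly the 200–400 Hz band that a network can
learn to detect directly from the waveform.

## The method

A recording sampled at rate `fs` is band-pass filtered (default: zero-phase
4th-order Butterworth, 20–500 Hz), resampled to the canonical 2000 Hz,
peak-normalized, and cut into 4-s segments `x_{i,j}` (8000 samples; trailing
partial windows are wrap-padded, exploiting cardiac periodicity). Class
imbalance is repaired by pitch-shifting minority-class segments — every
spectral component moves from `f` to `f·factor` (default factor 800/650)
with duration preserved. Segments split 70/15/15 into train/validation/test
by *sequential* rounding (`n_test = round(0.15·N)`, then
`n_val = round(0.15·(N − n_test))`), stratified by class and grouped by
source recording.

The classifier is six blocks of

    conv1d(F_l, kernel 3, same padding) → batch norm → ReLU → max-pool(2) → dropout(0.25)

with filters `F = (64, 128, 128, 64, 32, 16)`, then
`flatten → dense(128) → ReLU → dropout(0.5) → softmax` (a sigmoid head is a
config switch). It is trained with Adam (`η = 10⁻³`) on cross-entropy

    L = −(1/N) Σᵢ [ yᵢ log(ŷᵢ) + (1 − yᵢ) log(1 − ŷᵢ) ]

and evaluated with abnormal as the positive class; the ROC is swept over
every distinct score and `AUC = ∫ TPR d(FPR)` by the trapezoid rule, which
the tests verify equals the Mann–Whitney pair statistic. The compute kernels
(forward and backward) are RcppArmadillo; the backward pass is checked
against finite differences in the test suite.

## A worked example

```r
library(pcgnet)

# simulate a small labeled cohort: 20 normal + 20 abnormal 10-s recordings
cfg <- synth_config(seed = 1)
signals <- generate_signals(n_normal = 20, n_abnormal = 20, cfg)

# filter (20-500 Hz), resample to 2000 Hz, normalize, cut into 4-s segments
dataset <- preprocess_recordings(signals)
dataset
#> <pcg_dataset> 120 segments (60 normal, 60 abnormal)

split <- split_dataset(dataset, test_frac = 0.15, val_frac = 0.15, seed = 2)
split
#> <pcg_split> train 87 / val 15 / test 18 (seed 2, sequential rounding)

model <- build_model(model_config(input_len = 8000, seed = 3))
model <- train_model(model, split$train, split$val,
                     train_config(epochs = 8, seed = 4))
tail(model$history, 3)
#>   epoch train_loss train_acc  val_loss   val_acc
#> 6     6  0.5444473 0.7241379 0.4434444 0.7333333
#> 7     7  0.5733776 0.7471264 0.5413016 0.7333333
#> 8     8  0.3888260 0.8390805 0.3454898 0.9333333

report <- evaluate_model(model, split$test)
report$confusion_obj
#> <pcg_confusion> tp=8 tn=7 fp=2 fn=1 (n=18)
report$metrics$accuracy
#> [1] 0.8333333
cat(sprintf("held-out AUC: %.3f\n", report$auc))
#> held-out AUC: 0.877
```

Eight epochs on 87 four-second segments already separate the classes well
above chance (accuracy 0.83, AUC 0.88 on 18 held-out segments); the
acceptance-scale study below (50 + 50 recordings, 10 epochs) reaches
held-out accuracy ≥ 0.95 and AUC ≥ 0.98. Training loss falls from ~1.2 to
~0.4; validation accuracy at the final epoch is 0.93.

A command-line workflow wrapping the same functions ships in
`inst/cli/pcgnet`:

```sh
pcgnet simulate   --out data --n-normal 400 --n-abnormal 400 --seed 1
pcgnet preprocess --manifest data/manifest.csv --out store.rds
pcgnet train      --store store.rds --out run/ --seed 1
pcgnet evaluate   --checkpoint run/checkpoint.rds --store run/test_store.rds --out report.json
```

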