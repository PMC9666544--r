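# seizevision

Automated preprocessing and action-recognition classification of epileptic
seizures from bedside 3D video (pixel-aligned 512 x 424 depth + infrared at
30 fps), for researchers building computer-vision support tools for epilepsy
monitoring units. The package turns raw depth/IR stacks into cross-validated
seizure-type classification metrics for three classes — frontal-lobe
epilepsy (FLE), temporal-lobe epilepsy (TLE), and non-epileptic
pre-/post-ictal segments (Prepost) — and ships a synthetic scene generator
with pixel-level ground truth so every stage is testable without clinical
data.

## What it computes

**Depth-band cropping.** After closing zero-valued depth pepper noise by
grayscale dilation (4 x 4 rectangle, 2 iterations), 2nd-order polynomials
are fitted to the per-axis non-zero minimum and maximum depth profiles of
the first frame. The axis whose max-profile fit has the smaller |a₂| is the
bed's length direction; the patient line is the stationary point
−a₁ / (2 a₂) of the cross-axis min-profile fit. A 1st-order fit to the
depths along that line, offset by ± max(2σ, 100 mm), defines two parallel
planes; pixels with depth outside [near(t), far(t)] are removed from the
depth and IR streams, eliminating background and near-camera occluders
(attending clinicians).

**Bounding-box cropping.** The highest-confidence person and bed detections
on the first depth-cropped IR frame are merged into their union rectangle,
expanded by +30% per side, and applied to the whole video. Dataset variant A
applies the box to the raw IR stream, B to the depth-cropped stream (same
box), B0.5 additionally slices with 50% overlap.

**Sampling and features.** Videos are min-max converted to 8-bit, resized
(aspect-preserving bilinear, largest side 224) and padded, replicated to
3 channels, rescaled by 2x/255 − 1 to [−1, 1], and sliced into 60-frame
(2 s) windows, keeping trailing windows of ≥ 10 frames. Each clip becomes a
7 x 1024 feature sequence, pre-padded with −1 sentinel rows that a masking
layer hides from the classifiers.

**Classification and evaluation.** An LSTM-FC classifier (LSTM 128/64, FC
64/32 with batch norm, dropout 0.5, recurrent dropout 0.3; extended variant
128/128 + 128/64; sigmoid head with weighted MSE for 2 classes, softmax
head with weighted categorical cross-entropy for 3) and a retrained
average-pooling head are trained with inverse-frequency class weights
(w_c = N / (C n_c)), Adam (lr 0.001) or momentum SGD, and early stopping on
validation macro-F1. Evaluation is subject-grouped 5-fold cross-validation
(all of a patient's clips on one side of every split) reporting
macro-averaged F1/precision/recall and per-class sensitivity/specificity as
mean ± sd over folds. The neural layers, losses and optimizers are
implemented in the package as plain BLAS-backed matrix arithmetic, with
gradients verified against finite differences in the tests.

## Worked example

```r
library(seizevision)

# Synthetic EMU dataset: 6 patients per class, 2 seizures each
ds <- generate_dataset(c(FLE = 6, TLE = 6, Prepost = 6),
                       seizures_per_patient = 2, length_range = c(90, 150),
                       height = 106, width = 128, seed = 11)

cfg <- pipeline_config(variant = "B", n_classes = 3, arch = "lstm",
                       target_size = 96,
                       train = train_config(epochs = 120, batch_size = 16),
                       seed = 5)
store <- run_preprocess(ds, cfg)
print(store)
#> Sample store: 87 clips from 36 videos (variant B)
#>   crop success 36/36, detection success 36/36

features <- run_extract(store)
print(features)
#> Feature store: 87 sequences of 7 x 1024 (FLE:31, Prepost:27, TLE:29)

report <- run_experiment(features, cfg)
print(report)
#> 5-fold subject-grouped CV, lstm classifier, 3 classes (FLE, TLE, Prepost)
#>   macro-F1: 0.973 +/- 0.060
```

The preprocessing log reports per-video crop and detection success (the
depth crop falls back to a manual-crop error path on degenerate scenes);
the report holds per-fold macro metrics, per-class sensitivity/specificity,
confusion matrices and the patient-disjoint fold assignments. A macro-F1
near 1 on synthetic data says the pipeline's geometry, masking, weighting
and evaluation machinery are correct — synthetic motion statistics are far
cleaner than real video features, so this is not a clinical performance
claim.

A thin CLI over the same functions lives in `inst/cli/seizevision.R`
(`synth` and `run-all` subcommands).

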