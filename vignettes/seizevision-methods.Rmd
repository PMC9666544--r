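---
title: "Methods: 3D-video preprocessing and seizure classification in seizevision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D-video preprocessing and seizure classification in seizevision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-term video-EEG monitoring in epilepsy monitoring units (EMUs) produces
enormous amounts of bedside video that specialised clinicians review by eye.
The observable movement patterns of a seizure (its semiology, in particular
short "movements of interest" with class-specific frequency, amplitude and
dynamics) carry diagnostic information about the seizure type: frontal-lobe
epilepsy (FLE) seizures show faster movements than temporal-lobe epilepsy
(TLE) seizures, and non-epileptic pre-/post-ictal segments (Prepost) show
slow, low-amplitude activity, often with clinical staff moving around and
occluding the camera. `seizevision` implements, as reusable and tested R
code, an automated pipeline from raw pixel-aligned depth + infrared (IR)
stacks (512 x 424 px, 16-bit, 30 fps, depth in millimetres with 0 marking a
missing measurement) to cross-validated classification metrics:

1. depth-stream denoising and **depth-band cropping** that removes the
   background and near-camera occluders,
2. detector-driven **bounding-box cropping** around the patient and bed,
3. **temporal slicing** into 2-second (60-frame) clip samples,
4. **feature-sequence** preparation (7 timesteps x 1024 features, masked
   pre-padding), and
5. **LSTM-FC / average-pooling classifiers** with weighted losses, trained
   and evaluated under subject-grouped 5-fold cross-validation with
   macro-averaged metrics.

Clinical 3D-video recordings of seizures cannot be shared, so the package
ships a first-class synthetic scene generator that emulates the acquisition
geometry and provides pixel-level ground truth; every stage is validated
against it.

## Depth-band cropping

The depth stream carries zero-valued "pepper" noise (missing measurements).
These holes are closed by grayscale morphological dilation with a 4 x 4
rectangular structuring element applied for 2 iterations
(`denoise_depth()`). Because 4 is even, the window is anchored one pixel
above/left of centre (rows/cols `i - 1 .. i + 2`); the dilation is computed
as a separable running maximum, so the output is pointwise no smaller than
the input and the number of missing pixels never increases.

Cropping (`depth_crop()`) assumes the usual EMU arrangement: a wall-mounted
camera tilted roughly -45 degrees looking across a bed. On the first frame,
the per-index minimum and maximum of the non-zero depths are extracted along
both image axes and a 2nd-order polynomial is least-squares fitted to each of
the four profiles (`fit_axis_profiles()`; indices with no usable pixels are
excluded, and fewer than three usable indices on an axis is a
degenerate-geometry error). Along the bed's length the background is the
wall-bed transition, nearly flat, while across the bed it is a
floor-bed-floor transition with strong curvature, so the axis whose
max-profile fit has the **smaller |a2|** is the bed axis
(`select_bed_axis()`; an exact tie resolves to rows). The line on which the
patient lies is the stationary point of the cross-axis minimum-profile
quadratic, rounded to the nearest index (`locate_patient_line()`). When the
fit has no trustworthy vertex — |a2| below tolerance, a concave fit, or a
vertex outside the frame — the argmin of the raw minimum profile is used
instead; the paper-style vertex rule does not define these degenerate cases,
so the fallback is our design choice.

From the patient line, `compute_crop_planes()` fits a 1st-order polynomial
to the non-zero depths along the line (the bed/patient modelled as a flat,
possibly tilted slab) and offsets it by twice the standard deviation of
those depths on both sides, defining a near and a far plane. Two details are
deliberately configurable because the procedure's description leaves them
open:

* sigma uses **population** normalisation by default (it summarises the
  depths actually on the line, not a sample from a larger population);
  `sd_type = "sample"` is available;
* sigma is taken over the raw line depths, not over fit residuals;
* a perfectly flat line would collapse the band to zero width, so the
  half-width is floored at `min_halfwidth_mm` (default 100 mm, roughly half
  a patient's body height above the mattress).

A pixel is kept iff it is non-zero and its depth lies within
`[near(t), far(t)]` at its bed-axis coordinate `t` (`apply_depth_crop()`);
the cropped depth then masks the IR stream (`crop_ir_with_depth()`). Planes
are computed once on the first frame and reused for the whole video;
`per_frame = TRUE` refits them on every frame for scenes where the patient
moves through depth. The denoised stream is used both for plane fitting and
for the final masking.

One consequence worth knowing: dilation is a max filter, so at the boundary
of a *near-camera* occluder it overwrites a ring (up to ~6 px for the 4 x 4
element twice) with the depths behind it. Those ring pixels then lie inside
the band and survive the crop. On noise-free input there is nothing to
denoise and the recovery experiments therefore disable the dilation stage,
where occluder removal is exact; with pepper noise present the dilation is
required and the contamination stays confined to that thin ring.

## Bounding-box cropping

A person/bed detector is run on the first frame of the depth-cropped IR
stream. The detector is an interface (`detect()`): tests and synthetic
experiments use `oracle_detector()`, which reads boxes from the scene's
ground truth; `pretrained_detector()` is a stub that raises a capability
error, to be replaced by an adapter around an instance-segmentation model
where one is available. The highest-confidence person box and
highest-confidence bed box are merged into their union rectangle
(`select_and_merge()`); confidence ties resolve to input order, and if only
one of the two labels was detected its box is used alone (logged — the
procedure's behaviour for this case is not defined, so the degradation rule
is ours). The merged box is expanded by +30% of each dimension's extent on
every side, rounding half away from zero and clamping to the frame
(`expand_box()`), to keep violent movements inside the crop. The same
expanded box crops every frame of the video — and, in dataset variant A, the
*raw* IR stream, so that variants A (box crop only) and B (depth + box crop)
differ exactly in the depth-cropping step and in nothing else.

Coordinates throughout the package are 1-based with inclusive ranges, the
native R matrix convention.

## Clip sampling

Cropped videos are converted to 8-bit by per-video min-max scaling (a
constant video maps to 0; the radiometric mapping for the 16-to-8-bit step
is unconstrained, and per-video scaling preserves relative intensities over
time), resized with aspect-preserving bilinear interpolation so the largest
dimension is 224 px (the minor dimension rounds half up), zero-padded
symmetrically to 224 x 224 with any odd pixel on the bottom/right,
replicated to three identical channels, and rescaled to [-1, 1] via
`2 x / 255 - 1` — so padding becomes -1 after rescaling. The bilinear
resampler uses pixel-centre alignment and is implemented in the package so
the rounding and padding conventions are exactly the documented ones.

Temporal slicing (`slice_windows()`) cuts each video into 60-frame windows
(2 s at 30 fps) at stride `60 * (1 - overlap)` with `overlap` 0 or 0.5, and
appends a final shorter window iff at least `min_leftover` frames remain.
The boundary is read as *more than 9 frames*, i.e. a minimum leftover of 10;
because the source description elsewhere also mentions "9-60 frame" samples,
the threshold is a visible configuration parameter rather than a constant.
For `overlap = 0` the window count obeys the closed form
`floor(L / 60) + [L mod 60 >= 10]`, which the tests verify against
enumeration for every length up to 500.

## Feature sequences

Clips are turned into fixed-shape sequences of `k` timesteps x 1024
features, `k = clamp(floor(L / 8), 1, 7)`. Only `60 -> 7` is externally
fixed (the temporal stride of the 3D-convolutional backbone the features
mimic); the clamped floor rule reproduces it and degrades gracefully for
shorter clips, but it is an assumption — an adapter around a real backbone
must not rely on it for `L < 60`. Sequences shorter than 7 timesteps are
**pre-padded** with rows of -1 (`pad_features()`); -1 is reserved as the
masking sentinel and the extractor nudges any real value that would collide
with it.

The in-package extractor (`mock_extractor()`) is a deterministic stand-in
for a pretrained spatio-temporal network: per 8-frame block it pools
intensity statistics and motion statistics (mean/max/sd of absolute frame
differences and of intensity-centroid displacement, which together encode
oscillation frequency and amplitude) and projects them to 1024 dimensions
through a fixed seed-determined random matrix. This keeps synthetic classes
linearly separable while preserving the interface of a real backbone. What
it does *not* capture — posture, appearance, texture dynamics, limb-level
kinematics — bounds what synthetic experiments can show: they validate the
pipeline's plumbing, losses, masking and evaluation protocol, not clinical
classification performance.

## Classifiers and training

`build_lstm_classifier()` assembles: masking of -1 timesteps, LSTM(128),
LSTM(64), then twice [batch normalisation, dropout 0.5, fully connected
ReLU] with 64 and 32 units, and a prediction head — one sigmoid unit for
the 2-class case, three softmax units for the 3-class case. The extended
variant uses LSTM 128/128 and FC 128/64. Recurrent dropout is 0.3, FC
kernels use He-uniform initialisation, and L2 regularisation is applied to
LSTM/FC kernels, recurrent weights, LSTM activity and FC biases. The L2
coefficients are not pinned by the source description; they default to
1e-4 everywhere and are arguments. Activity regularisation is applied per
LSTM layer output (another open point, flagged in the argument docs), and
no BN/dropout is inserted *between* the LSTM layers. Batch normalisation
precedes dropout, avoiding the train/test variance shift of the reverse
order.

Losses are weighted mean squared error (2-class, targets encoded 0/1) and
weighted categorical cross-entropy (3-class): the per-sample loss is
multiplied by its class weight and averaged. Class weights are inverse
frequency, `w_c = N / (C n_c)` (mean 1 under balance) — the exact weighting
formula is not given in the source, and this is the standard choice.
Optimisation uses Adam (lr 0.001, beta1 0.9, beta2 0.999) for the LSTMs and
momentum-0.9 SGD for the average-pooling head (`build_i3d_head()`, whose
temporal mean excludes masked timesteps and whose linear layer has
`1024 c + c` trainable parameters). After every epoch the validation
macro-F1 is recorded and the best epoch's parameters are kept (early
stopping; ties keep the earliest).

Because no deep-learning framework is assumed, the layers, losses and
optimizers are implemented inside the package as plain BLAS-backed matrix
arithmetic, with backpropagation through time under masking. The gradients
are verified against central finite differences in the test suite (relative
error below 1e-4 on sampled coordinates of every parameter tensor, with
stochastic layers disabled). Training is fully seeded — shuffling, dropout
masks and initialisation all derive from the config seed — so runs are
bit-reproducible on a fixed BLAS/thread configuration.

Reference-scale training (2000 epochs, batch 500/1000) is available through
`train_config()`; the package's own experiments default to a desk scale of
300 epochs with batch 16, which gives the optimiser enough updates on
datasets of ~100 clips while early stopping guards against overfitting.

## Evaluation

`make_cv_folds()` builds subject-grouped folds: all clips of a patient land
on one side of the split, preventing identity leakage. Each fold's
validation set holds a fixed number of patients per class (the reference
setting is 3 FLE + 3 TLE from pools of 15 and 11). When a class pool
divides exactly, folds partition it (each patient validated once); when the
pool is short — 5 folds x 3 TLE slots > 11 patients — slots are filled
without replacement until the pool is exhausted and then replenished, so
every patient is validated at least once. The assignment policy for the
short-pool case is not described in the source; exhaust-then-replenish is
our choice because it is the weakest form of repetition that still touches
every patient.

Metrics are macro averages: one-vs-rest precision/recall/F1 per class
averaged with equal class weight (`macro_metrics()`), plus per-class
sensitivity and specificity (`sensitivity_specificity()`). Zero
denominators yield 0 with a flag rather than NaN. Fold summaries report the
mean and *sample* standard deviation (n - 1) across folds. Metrics are
computed clip-wise (each 2-s sample counts once); seizure-level aggregation
by majority vote is easy to add on top of the per-clip predictions but is
not the primary protocol.

## The synthetic scene generator

`generate_scene()` renders a procedural EMU scene rather than a mesh: a
background whose depth is quadratic across rows (floor-bed-floor, curvature
scaled by the camera tilt's tangent) and linear across columns (wall-bed), a
planar bed slab at `bed_depth_mm` spanning the frame width, an ellipsoidal
patient bump (2/3 of the band half-width deep) whose centre oscillates
laterally at `motion_freq_hz`, i.i.d. pepper zeros at `pepper_fraction`, an
IR image that is a deterministic function of depth plus a texture on the
patient, and an optional square occluder at a configurable near depth
(present in the second half of the frames by default, like a clinician
stepping in). Ground truth includes per-frame patient masks, the bed box
and the depth band bracketing all noise-free patient/bed depths. Everything
is seeded and bit-reproducible.

`generate_dataset()` draws per-patient motion frequencies from
class-conditional ranges — TLE 0.4-1.8 Hz, FLE 2.0-2.8 Hz (faster than
TLE, and kept disjoint so that class labels are learnable from motion
alone), Prepost 0.1-0.4 Hz at a third of the amplitude plus occluder
events — with small per-seizure jitter. The patient-level draw matters: under
subject-grouped validation a patient drawn near a class boundary is a
genuinely hard case, and desk-scale runs do show occasional imperfect folds.

What the generator does **not** emulate: real body shapes and articulated
movement, blankets and bed rails, IR noise and illumination changes,
multiple beds, camera motion, or any appearance correlate of seizure type.
Passing tests on synthetic scenes therefore demonstrate the correctness of
the geometry, masking, slicing, training and evaluation machinery — not
clinical performance, whose headline numbers require the private clinical
recordings and a pretrained video backbone.

## Problem sizes used by tests and scripts

The test-suite experiments run at reduced, stated sizes chosen as the
package's own desk scale: scenes of 64 x 80 to 424 x 512 px with 2-8
frames for geometry checks; and for the end-to-end recovery experiment a
3-class dataset of 6 patients per class x 2 seizures of 90-150 frames at
106 x 128 px, clips resized to 96 px, standard LSTM, 300 epochs, batch 16,
subject-grouped 5-fold CV. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed and writes the
recovered quantities (depth-crop IoU, occluder removal, crop success rate,
2- and 3-class CV macro-F1) as JSON.

## Known limitations

* The mock extractor's features are far cleaner than real video embeddings;
  expect the reported synthetic macro-F1 to be optimistic relative to any
  real-data replication.
* The depth-crop algorithm assumes a single bed roughly aligned with an
  image axis and a tilted-camera background; it has a manual-crop error
  path, not an automatic recovery, when those assumptions fail.
* The timestep rule for clips shorter than 60 frames is an assumption of
  the mock extractor, not a property of any specific pretrained backbone.
* Batch-norm statistics make training batch-composition dependent;
  reproducibility is exact only for a fixed seed, batch size and thread
  configuration.
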