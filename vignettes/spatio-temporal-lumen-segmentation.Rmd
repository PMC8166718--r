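---
title: "Spatial-temporal ensemble segmentation of the endoscopic lumen"
author: "LumenSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal ensemble segmentation of the endoscopic lumen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LumenSeg)
```

# The problem

During ureteroscopy the navigable path of the endoscope is the hollow lumen,
which appears as the darkest, roughly tunnel-shaped region of the field of
view. Automatic per-frame lumen segmentation supports navigation and, in
robotic settings, provides the control signal for steering. The difficulty is
not the typical appearance — a dark blob on a brighter, reddish wall — but
the artifact load of real endoscopic video: specular highlights, floating
debris, motion and focus blur, bleeding tint, and frames in which the view is
transiently occluded altogether.

`LumenSeg` implements a spatial-temporal ensemble for this task. Four
segmentation models run in parallel and their per-pixel probability maps are
averaged:

* **m1** — a single-frame residual U-Net,
* **m2** — a single-frame instance-segmentation core behind an
  instance-to-lumen adapter,
* **M1, M2** — multi-frame extensions of the two cores, each prepended with
  one 3D convolution that ingests the frame triplet
  $[I(t-1), I(t), I(t+1)]$ and emits features for the central frame.

The ensemble function is the arithmetic mean of the $k$ member predictions,

$$F(p_i(t)) = \frac{1}{k}\sum_i^k p_i(t),$$

computed on soft probabilities, not pre-thresholded masks, and binarized at
0.5 afterwards. The rationale for mixing single- and multi-frame members is
that consecutive frames change minimally but carry complementary evidence:
debris that crosses the field of view in one frame, a specularity that
appears and disappears, a transiently occluded view — in all these cases
the temporal neighbours contain information the central frame lacks, while
clean frames are segmented at least as well by the single-frame cores.

# Models

## The residual U-Net core (m1)

`buildResUNet()` constructs an encoder–decoder with skip connections in
which every block is a *residual unit*: two 3×3 convolutions (batch
normalization on by default) with an identity shortcut, using a 1×1
projection where channel counts change. Filters start at `baseFilters` and
double per level; downsampling is 2×2 max pooling, upsampling a 2×2
transposed convolution; a final 1×1 convolution and sigmoid yield one
probability channel. Inputs must be divisible by `2^depth`.

The forward and backward passes are implemented in the package itself
(im2col + GEMM convolutions in RcppArmadillo, hand-derived gradients,
verified against central finite differences in the test suite), so the whole
training loop is self-contained and deterministic given a seed. The head
bias is initialized at −2: starting the predicted foreground probability
near the low prior of lumen pixels avoids the large initial false-positive
mass that slows Dice-loss training when predictions start at 0.5.

Training minimizes the **soft Dice loss**

$$L_{DSC} = 1 - \frac{2\,TP}{2\,TP + FN + FP},$$

with soft counts (sums of products of probabilities and labels) and a
smoothing epsilon of 1e−6, per sample, averaged over the batch. Evaluation
always uses hard counts. The optimizer is Adam (a standard choice for
Dice-loss segmentation) with a cosine learning-rate decay to 5% of the base
rate over the epoch budget. Pure-Dice optimization of small foregrounds is
sensitive to the starting basin, so two robustness devices standard in
iterative optimization are on by default: a **multi-start probe** (the
`nstart` idiom — candidate initializations train for a couple of epochs and
the one with the best validation DSC continues) and **Polyak averaging**
(an exponential moving average of the weights, decay 0.995 per step, used
for validation and checkpoints). Inputs are standardized per frame and
channel at the model entry, so the cores learn contrast rather than
absolute colour; the checkpoint with the best validation DSC is retained.

## The instance core (m2) and its adapter

The second core is a detector-style instance segmenter: it emits candidate
instance masks with confidence scores, and the adapter
`instancesToLumenMap()` reduces them to one lumen probability map —
instances below the minimal detection confidence are dropped; `"best"` keeps
the highest-scoring survivor (the lumen is a single region in this anatomy),
`"union"` takes the pixelwise maximum (kept for ablation). The proposal
generator here is classical: the luminance channel is smoothed, thresholded
at a ladder of darkness quantiles (the lumen is the least-illuminated region
of the FOV), and connected components become soft masks scored by darkness
contrast and compactness. Anchor scales (defaults 32, 64, 128, 160) bound
the plausible instance area; the minimal detection confidence is swept over
0.5–0.9 in steps of 0.1 during fitting, together with the smoothing width.
The backbone label (`resnet50`/`resnet101`) is part of the configuration
surface shared with detector-style implementations and does not alter the
classical generator.

## The temporal extension (M1, M2)

A core model `m` becomes a multi-frame model `M` by prepending a single 3D
convolution with `nK` kernels of size $(r \times 3 \times 3)$, $r = 3$,
applied to the frame triplet. The valid convolution consumes the whole
temporal extent, leaving an output of shape $(1, p-2, q-2, n_K)$; a
one-pixel zero ring restores $(p, q, n_K)$ so the core's input contract is
unchanged, and the singleton temporal axis is squeezed. The zero ring is
symmetric (one pixel on each side); the activation after the front is ReLU
by default with a linear option for ablation.

For M1 the front is He-initialized and trained end-to-end with the core;
`nK` must equal the core's input channels and is a searched hyperparameter
(default search set {3, 8, 16}; the package default is 3, which keeps the
core identical in shape to the RGB one). For M2 the fixed-input core only
admits `nK = 3`, enforced at configuration time; its front is initialized as
the across-time mean of each colour channel — a temporal denoiser — and
stays at that initialization because the classical core provides no gradient
path. No normalization is inserted between the front and the core; the
core's own first batch-norm layer fills that role for M1.

# Data handling

**I/O.** Frames are read from PNG/JPEG directories, ordered by the numeric
part of their filename stems, normalized to $[0,1]$ by the decoder's bit
depth. Frames of one video must share spatial dims; videos may differ
(clinical collections do), and sizes are unified by resizing inside the
prediction/training pipeline (bilinear for images, nearest-neighbour for
masks), never at read time. Masks follow the `<stem>_mask.png` convention,
foreground 255. Video containers are not decoded in this build — frames are
extracted to directories first.

**Triplets.** At video boundaries the edge frame is replicated by default
(`replicate_edge`), so every annotated frame is a triplet center and the
single- and multi-frame models score the same frame set; `drop_edges` is
available for strict-causality experiments.

**Augmentation** is offline (before training): quarter-turn rotations
(uniform over 0/90/180/270°), fair horizontal and vertical flips, and zoom
uniform in ±2%. One parameter draw is applied identically to the image (or
to all three frames of a triplet — temporal coherence) and to its mask;
images are resampled bilinearly, masks nearest-neighbour so they stay
binary. Zoom-in center-crops and zoom-out zero-pads back to the original
size. At zoom 1 the transform is an exact pixel bijection, which the tests
exploit (TP counts are conserved under joint transformation). Augmented
copies inherit the source frame's patient, keeping patient-wise folds
leak-free. The number of copies per original is configurable (default 4).

# Training protocol

Hyperparameters are selected by **patient-wise five-fold cross-validation**
in a grid search — learning rates {1e−3, 1e−4, 1e−5, 1e−6} crossed with
batch sizes {4, 8, 16} (plus `nK` for M1) — selecting the highest mean
validation DSC, ties broken by smaller learning rate then smaller batch
size, so the selection is re-derivable from the emitted CV table. The final
fit uses the selected values on all training patients' frames with a
**60/40 frame-random train/validation split** (stratified by video;
a patient-wise option exists) for checkpoint selection. A master seed fans
out deterministically to data shuffling, augmentation and weight
initialization through a counter-based scheme, so the whole pipeline is
reproducible on one machine.

# Metrics and comparison

Per frame, predictions are binarized (threshold 0.5 — the natural decision
boundary for a mean of probabilities) and scored by DSC, precision and
recall from the pixel confusion counts. Conventions for degenerate frames:
when both masks are empty, all three metrics score 1 (agreement on absence);
an empty prediction against a non-empty reference scores 0. Reported numbers
are means over frames of per-frame metrics (matching per-frame box-plot
summaries), not pooled-pixel statistics. Models are compared with the
Kruskal–Wallis test on per-frame DSC, with pairwise stars at 0.05/0.01/0.001.

# The synthetic video generator

Real ureteroscopy data are patient data and cannot ship with a package, so
`generateVideo()`/`generateDataset()` synthesize videos that reproduce the
*statistical structure* the models exploit:

* a reddish textured wall (sum of low-frequency sinusoids, per-video hue),
* radial illumination falloff around the lumen center,
* a dark elliptical lumen whose center drifts smoothly
  (amplitude 9 px, ~0.15 rad/frame at 64×64) and whose ground-truth mask is
  the exact ellipse interior — chosen over free-form blobs because the
  ellipse admits a closed-form area oracle for testing; a harder deformable
  option can be emulated by raising the radius jitter,
* artifacts drawn per frame: specular white blobs (placed outside the
  mask), semi-transparent drifting debris, Gaussian blur, bleeding tint,
  and optional full-frame noise corruption of isolated center frames.

Corrupted frames are never adjacent, so their temporal neighbours stay
clean — exactly the situation where a triplet model has information a
single-frame model cannot recover. In every clean frame the mean intensity
inside the mask is strictly below the mean outside, so the task is learnable
by construction. The default fixture is 11 videos over 6 synthetic patients
(2, 2, 1, 1, 1, 4 videos each) at 64×64 — structured like a small clinical
collection, small enough for desk-scale CPU training. All randomness flows
from one master seed through counter-based per-video sub-seeds, so each
video's content is independent of generation order.

What the generator does **not** emulate: real tissue texture statistics,
specular geometry of wet mucosa, fluid motion, peristalsis, camera optics.
Passing the package's tests therefore demonstrates that the implementation
is correct and that the temporal mechanism works as designed — not that the
models reach any particular accuracy on clinical video.

# Numerical and design choices

* Working resolution: both cores consume a fixed square input (64×64 in the
  desk-scale experiments; 256×256 is a realistic clinical setting);
  predictions are resized back to native frame size before scoring.
* Convolutions run in single precision internally (the standard numerical
  regime for CNN training); everything else is double precision.
* Binarization threshold 0.5 throughout; member maps are averaged soft.
  `selectThreshold()` offers validation-based operating-point calibration,
  mirroring the instance core's confidence sweep.
* Soft-Dice epsilon 1e−6 — small enough not to perturb the third decimal of
  the loss at 64×64.
* Batch-norm: momentum 0.1 on running statistics, eps 1e−5; inference uses
  running statistics, making prediction deterministic.
* Adam defaults β₁ = 0.9, β₂ = 0.999, eps 1e−8.
* Grid-search ties: smaller learning rate, then smaller batch size.
* Desk-scale problem sizes used by the test suite and the acceptance
  script: ~300 training frames at 64×64, depth-3/base-16 residual U-Net
  (~0.5 M parameters), ≤ 15 epochs; the corrupted-fixture experiment uses a
  30% per-frame corruption rate. These sizes were chosen so a full run
  trains in minutes on one CPU while leaving the learnability and
  temporal-recovery effects clearly measurable.

# Known limitations

* The instance core is a classical proposal generator, not a learned
  detector; it shares the adapter contract and configuration surface of
  detector-style implementations but not their capacity. M2 correspondingly
  keeps a fixed temporal-averaging front.
* Only $r = 3$ temporal extents are supported, by design.
* The training loop is single-threaded CPU code; it is meant for method
  study and desk-scale experiments, not clinical-scale training.
* Video containers must be pre-extracted to frame directories.

# A worked desk-scale run

```{r, eval = FALSE}
ds <- generateDataset(nVideos = 11, framesPerVideo = 30, seed = 101)
sp <- splitByPatient(ds, "patient5")     # held-out synthetic patient
tv <- splitTrainVal(sp$train, 0.6, seed = 101)

m1 <- buildResUNet(ResUNetSpec(depth = 3, baseFilters = 16,
                               inputShape = c(64, 64, 3)), seed = 101)
fit <- trainModel(m1, tv$train, tv$val, lr = 1e-3, bs = 4, epochs = 10,
                  seed = 101)
tail(fit$history, 3)

preds <- lapply(sp$test$frames, function(f)
  binarize(predictSingle(fit$model, f)))
mean(evaluateFrames(preds, sp$test$masks, "m1")$dsc)
```

The README shows the figures this run actually prints; the acceptance
script (`scripts/acceptance.R`) reruns the full pipeline — fixture
generation, training of m1 and M1 on a corrupted fixture, the instance core
fit, and the 4-member ensemble — from one seed and writes the measured
quantities as JSON.
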