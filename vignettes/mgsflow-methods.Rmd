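---
title: "mgsflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mgsflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Post-surgical pain in laboratory mice is routinely under-detected by
cage-side inspection. The mouse grimace scale (MGS) scores five facial
action units — orbital tightening, nose bulge, cheek bulge, ear position and
whisker change — each as 0 (absent), 1 (moderate) or 2 (severe), and is far
more sensitive, but manual scoring is slow and rater-dependent. `mgsflow`
implements the analysis side of an automated cage-side monitoring workflow:
standardized front-camera video is reduced to a handful of high-quality
face frames, each frame is cropped to the face and scored per component by a
multi-head classifier, and top-camera pose estimation feeds a behavioral
clustering ("behavior flow") analysis of how animals move between behavioral
motifs.

The package reproduces the *pipeline*: its selection rules, preprocessing
arithmetic, loss and training schedule, cross-validation design,
aggregation, file formats and statistics. The production-scale network
weights (a pretrained vision transformer for MGS, a YOLO-family face
detector, a mobilenet-family quality regressor) are deliberately out of
scope; backends are pluggable callables, and a tiny trainable reference
backbone ships for desk-scale studies on synthetic data.

# Stage by stage

## Frame quality and frame selection

The quality model contract is a single raw output mapped through a sigmoid
and scaled: `qualityFromRaw(r) = 6 * plogis(r)`, giving the continuous 0–6
scale used by the human annotations (0 unusable, 6 ideal; the scale folds
together visibility, head pose and motion blur).

Two published selection rules are implemented:

* **Segment rule** (`selectBySegments()`): the video is cut into
  consecutive segments of `round(interval_s * fps)` frames (defaults 10 s at
  30 fps = 300 frames); each segment contributes its highest-quality frame
  if that quality reaches the **4.25** threshold. Design choices the source
  text leaves open: the final partial segment is scored like any other
  (discarding it would throw away usable frames), and ties break to the
  lowest frame index. An all-below-threshold recording selects zero frames —
  a valid outcome, not an error.
* **Spacing rule** (`selectWithSpacing()`): greedy by descending confidence
  (ties to the lower index), a candidate needs confidence ≥ 0.5, accepted
  frames must be ≥ 80 frames apart, and at most 5 frames are kept. The
  source describes the criteria but not an algorithm; greedy descending
  confidence is the minimal deterministic reading and is cross-checked in
  the tests against an independently coded max-search oracle.

`gateByKeypointConfidence()` implements the pre-filter that discards frames
where *any* of the nose/ear keypoints falls below confidence 0.5.

## Face-crop geometry and preprocessing

Boxes are half-open `[x0,x1) x [y0,y1)` in pixel coordinates, origin
top-left. Intensities are floats in `[0, 1]`. Rounding to the pixel grid is
floor for the top-left and ceiling for the bottom-right — fixed so that
cropping is bit-reproducible.

Validation preprocessing (`validationPreprocess()`) is fully deterministic:
expand the detected box by 5% about its center, square it by growing the
smaller dimension, crop with zero padding, normalize by fixed corpus
statistics (`computeNormStats()`, pooled population mean/sd over the padded,
squared, cropped training images), and resize bilinearly to 224 × 224,
broadcasting the grayscale values into three identical channels.

Two readings of "expanded by 5% about the box center" are defensible: per
boundary (each dimension × 1.10) or per dimension (× 1.05). The default is
per boundary, which matches the phrasing of the training-time pipeline; the
alternative is exposed via `expandBox(..., perDimension = TRUE)`.

Training augmentation (`sampleTrainingAugmentation()`) applies, in order:
per-boundary box jitter up to ±10% with probability 0.5 (otherwise the fixed
5% expansion), squaring, zero-padded crop, horizontal flip (p = 0.5),
brightness ±15% (multiplicative) and contrast ±5%, a rotation branch
(p = 0.25 bilinear, p = 0.25 nearest, p = 0.5 none; angle uniform in ±10°),
fixed normalization, and a final resize that is bilinear or nearest with
probability 0.5 each. Contrast is defined about the patch mean
(`(x - m) * c + m`) and rotation about the patch center with zero-filled
corners — both unspecified in the source and fixed here. With every
stochastic branch disabled, the augmentation path reproduces the validation
path exactly (tested). Gaussian blur, rotation and resampling are delegated
to EBImage.

## The MGS classifier

The classifier contract is five 4-way heads (score 0 / 1 / 2 / NR). "Not
rateable" is a first-class class — a frame may show wet fur or an occluded
component — never missing data. The training loss is the **composite
cross-entropy**, the unweighted sum of the five per-head cross-entropies
(uniform predictions give `5 * ln 4 ≈ 6.93`); head weights are 1 each, per
"the sum". Decoding is per-head argmax with ties to the lower class index.

Optimization follows the published recipe: SGD with momentum 0.95, weight
decay 0, base learning rates 1e-4 (backbone group) and 1e-3 (heads group),
both decayed ×0.1 every 5 epochs (`scheduledLr()`, 0-based epochs), batch
16, 20 epochs with the epoch-10 state selected. Batches are reshuffled each
epoch from the run seed, making training reproducible. **Content
augmentation** (`contentAugment()`) adds each labeled frame's immediate
temporal neighbors with identical targets (assuming the expression varies
little within 1/30 s), tripling a fully neighbored set; missing neighbors
are skipped rather than duplicated (duplication would silently re-weight
classes), and validation sets are never augmented.

Cross-validation is **leave-one-animal-out** (`makeLoaoFolds()`): one fold
per animal, validation = that animal's frames, training = everything else,
so no animal leaks across the split. `makeAnimalFolds()` generalizes the
same animal-disjoint rule to k folds (as used for detector training).

The shipped **reference backbone** is a deliberately tiny network — block
mean pooling of the normalized input to a 14 × 14 intensity grid, one tanh
hidden layer (the "backbone" parameter group) and five linear heads — small
enough to train on one CPU in seconds per fold yet expressive enough to
recover the synthetic phenotypes. The `trainingConfig()` fields `hidden`
(2048/1024) and `dropout` (0.4/0.2) describe the published head stack and
travel in the config snapshot for full-scale backends; the reference
backbone does not use them.

## Session scoring and outputs

`scoreSession()` chains selection → detection → validation preprocessing →
classification. No-detection frames are dropped and logged in the session
metadata. Aggregation: the per-frame mean is the mean over *rateable*
components (NR excluded rather than imputed — the only rule that keeps means
on the 0–2 scale), undefined when all five are NR; the video mean averages
the defined frame means, excluding all-NR frames. The alternative pooling
(all component scores in one pass) is available via
`videoMeanMgs(..., pooling = "components")`. Undefined means serialize as
*empty* CSV fields, never 0, to avoid a silent "no pain" bias.

Each scored session writes three CSVs (`writeSessionOutputs()`): grimace
scores with frame numbers and timestamps, per-camera frame timestamps
(computed as `frame_index / fps`; the hardware timestamps of the original
device cannot be reproduced), and the pose track in the three-row-header
keypoint CSV dialect (scorer row, body-part row repeated ×3, x/y/likelihood
row). Numeric fields are written at full precision so the write → read round
trip is lossless.

## Behavior flow

`extractFeatures()` computes 41 per-frame features over the six mouse parts:
6 point accelerations (magnitude of the centered second difference of
position), 6 point speeds, 13 pairwise distances, 6 distances to the nearest
arena border (from the corner keypoints), 7 signed angles between segment
pairs, 2 shoelace polygon areas (head and body), and the body-axis angular
velocity — 41 in total. The *count* and the categories are fixed by the
source; the exact membership is not published (it defers to earlier work),
so the default manifest documents one concrete composition and is fully
configurable. Edge frames use replicated differences so every frame gets a
row.

`normalizeAndExpand()` z-scores each column over the fitting corpus (stored
for reuse; zero-variance columns pass through as zeros with a warning) and
concatenates the ±15-frame window, giving 41 × 31 = 1,271 expanded columns.
`fitClusters()` runs k-means (Lloyd) with k-means++ seeding — base R's
`kmeans()` lacks k-means++, so the seeding is implemented here — at the
published default of ten clusters. Transfer to recordings outside the
fitting sample defaults to nearest-centroid assignment (deterministic and
exactly consistent with the fit); the published pipeline's neural transfer
is available via `trainTransferClassifier()` (an `nnet` softmax network)
behind an argument. Labels are then smoothed with a five-frame sliding mode
filter; ties keep the original center label, avoiding order dependence.

Transition matrices count consecutive-frame cluster changes; the default
excludes self-transitions ("transitions between clusters"), with
`includeSelf = TRUE` exposed. `flowCompare()` normalizes each animal's
counts to proportions, takes the L1 distance between group mean proportion
matrices over ordered pairs i ≠ j as the overall statistic, and computes its
p-value by permuting animal group labels (add-one form, so p ∈ (0, 1]);
per-transition one-tailed two-sample z-tests are reported alongside. The
overall statistic and permutation scheme are this package's definition — the
source defers the test to companion software — and are validated here by
power and type-I simulation rather than by reference output.

`distanceMoved()` converts pixels to centimeters with an affine scale fitted
from the mean arena-corner positions against the physical 11 × 7 cm floor,
bridging low-confidence frames (< 0.5) by linear interpolation before
summing displacements.

# The synthetic-data generator

The generator is first-class, tested code: every downstream stage can be
trained and validated without animal data.

**Faces** are procedural — ellipses, rectangles and line strokes on a
grayscale canvas; no photographs. Each component score drives one monotone
geometric trait with a linear mapping: orbital tightening scales the eye
aperture by `1 − 0.4·score`; nose and cheek bulges brighten ridge/pad
ellipses by `0.11·score` and `0.10·score`; ear position drops and flattens
the ears by `0.14·score` of the face height; whisker change droops the
whiskers by 22°·score. "Not rateable" renders the component's region
occluded by a background-level block (the source gives NR a class but no
visual definition). Head implants and wet fur are drawn as a skull block and
dark streaks. Quality ground truth factorizes as `q = 6 · f(blur) · g(yaw)`
with piecewise-linear `f` (1 at σ = 0 → 0 at σ = 6 px) and `g` (1 at 0° → 0
at 60°): the 0–6 scale's semantics are published, its formula is not, and
this construction makes quality exactly 6 for a sharp frontal face and
monotone in both nuisances.

**Keypoint tracks** come from a regime-switching Markov model over four
kinematic states (immobility, locomotion bursts, rotation, a rearing proxy
expressed as posture foreshortening), each defining speed, turning-rate and
posture-scale distributions for a rigid six-part body plus four stationary
arena corners at 40 px/cm. The keypoint schema is a documented stand-in: the
original top-camera keypoint set is not published.

**Cohorts** mirror the analgesia-comparison design: groups "M" (NSAID only)
and "B+M" (opioid + NSAID), timepoints 0 h/4 h/24 h/48 h/72 h, default 8
animals per group, 10-min sessions at 30 fps (18,000 pose frames; 300
rendered front frames per session — rendering full-length synthetic front
video would add nothing). Effects are an additive MGS elevation (default
peak +0.8 at 4 h decaying to 0 by 72 h, both groups — the post-craniotomy
trajectory) and a locomotion multiplier (default 3 for B+M at 4 h — opioid
hyperactivity). The multiplier scales the locomotion state's speed *and* the
odds of entering it: a hyperactive animal both moves faster and spends more
time moving, which is what makes the effect visible to a transition-based
analysis at all.

**What passing tests do and do not show.** The synthetic faces are linearly
separable by design, with geometry noise far below real biological
variability; the LOAO recovery result (per-component held-out accuracy
≥ 0.8 with the tiny backbone) validates the *training machinery* — loss,
schedule, augmentation, fold construction, decoding — not real-world scoring
accuracy, which depends on the heavyweight backbones and real data that are
out of scope. Likewise the regime-recovery result validates the feature →
expansion → clustering → smoothing chain, not the semantics of real
behavioral clusters.

# Validation design and problem sizes

Desk-scale sizes were chosen so the whole suite runs in a few minutes on one
CPU; they are stated here as the package's own study sizes:

* **LOAO recovery**: 6 animals × 40 labeled frames (96 px renders, 64 px
  classifier input, 10 epochs with the epoch-10 state selected, otherwise
  the published optimizer settings). Content augmentation triples each
  fold's training set.
* **Regime recovery**: 6 recordings × 600 frames from
  `separableRegimeModel()`, k = 10 fit, labels majority-mapped onto the four
  true states before computing the adjusted Rand index (k = 10 deliberately
  over-segments 4 regimes, so raw ARI would conflate over-segmentation with
  error; a separable k = 3 blob fixture checks raw ARI = 1 separately).
  The recovery fixture has dwell times (~100 frames) well beyond the
  31-frame expansion window and widely spaced speeds — the realistic default
  cohort model switches regimes faster than the temporal window and is *not*
  expected to be recoverable at this ARI, which is a real limitation of
  windowed clustering, not a defect.
* **Flow-compare calibration**: power is estimated over 50 repetitions of
  the 3× locomotion effect (8 animals per group, 3,000 frames, 999
  permutations) and type-I error over 200 null repetitions (199
  permutations). These simulations draw behavior-state label sequences
  directly from the regime Markov chain: the statistic's operating
  characteristics are a property of the test given labels, and the label
  production chain is validated by the regime-recovery study; re-running the
  full pipeline inside every repetition would multiply runtime by orders of
  magnitude without changing what is being tested.

# Numerical choices and degenerate inputs

* Pixel grid rounding: floor(x0, y0), ceil(x1, y1); fully outside boxes
  yield all-fill patches, not errors.
* `computeNormStats()` uses the population (divisor n) convention and
  refuses an all-constant corpus.
* Normalization happens *before* resampling, matching the published order.
* k-means++ resamples among non-duplicate points if a zero-distance draw
  would duplicate a center; Lloyd iterations are capped at 100.
* Smoothing ties keep the center label; selector ties keep the lowest frame
  index; argmax decoding ties keep the lowest class index.
* Permutation p-values use the add-one estimator, so p = 1 for identical
  groups and p is never 0.
* Zero-length selections, empty sessions and all-NR frames are valid states
  that propagate as empty outputs / `NA` means, never as zeros.

# Limitations

* The reference backbone is a validation instrument, not a production
  scorer; real deployments plug in trained heavy backends behind
  `detectFace()` / `classifyComponents()` / the quality callable.
* The 41-feature membership, the transfer-network architecture and the
  overall flow statistic are documented local definitions where the source
  defers to companion software; all three are configurable.
* The synthetic renderer models one mouse, frontal pose, fixed lighting; it
  does not attempt photorealism, fur texture, or multi-animal scenes.
* Timestamps are reconstructed from frame indices; hardware capture
  timestamps are not modeled.
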