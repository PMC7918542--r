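---
title: "Depth-image body-joint detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-image body-joint detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthpose)
```

`depthpose` re-implements the processing pipeline of a depth-camera
body-joint detector: a single person walks toward a fixed, knee-height
640 × 480 depth sensor; each frame is converted to a point cloud, the
background is stripped, the remaining person is rendered to a gray image
and handed to a heatmap predictor; decoded keypoints are filtered for
visibility, placed in 3D via the depth image, and scored with the COCO
keypoint metrics. This vignette explains each model, the tunable
parameters, and the choices made where the design was genuinely open.

## Camera model and conventions

The camera is a pure pinhole: `u = f_x x / z + c_x`, `v = f_y y / z + c_y`,
with identity rotation and zero translation — the camera frame *is* the
world frame. Scene points carry `z < 0` (depth values grow in the negative
direction), and a rendered depth image stores `Im(u, v) = -z > 0` with 0
reserved for background/invalid pixels; all public APIs document this
sign convention. Pixels are rounded half-away-from-zero; pixel (0, 0) is
top-left, `u` rightward, `v` downward. When several points land on one
pixel the nearest to the camera wins, matching physical occlusion. Lens
distortion is out of scope (inputs are assumed pre-corrected), and no
mirroring is applied to depth renders: the negative-`z` projection already
produces the depth camera's native handedness.

Real intrinsics should come from a sidecar config (`read_intrinsics()`).
The synthetic default — `f_x = f_y = 600`, principal point (320, 240) — is
a documented stand-in, not a calibration.

## Preprocessing

The pipeline (`preprocess_scene()`) chains, in order:

1. **MLS smoothing**, search radius 0.03 m. Each point is projected onto a
   local least-squares plane through its neighbors within the radius. An
   order-1 (plane) fit with uniform weights is the minimal choice that
   matches the stated radius semantics; the order is deliberately not
   configurable beyond that. Points with fewer than 3 neighbors pass
   through unchanged, so the point count is preserved. Internally the
   plane normal is the smallest eigenvector of the neighborhood
   covariance, computed for all points at once as the dominant eigenvector
   of the covariance adjugate (exact for planar neighborhoods).
2. **Floor removal** by RANSAC plane segmentation, inlier threshold
   0.02 m, 1000 hypotheses, seedable, best plane by inlier count with ties
   to the first found, followed by a total-least-squares refit on the
   consensus set (the behavior of the usual PCL pipeline). Within
   `preprocess_scene()` the accepted plane must additionally be
   *floor-like*: its normal within 30° of vertical and its inlier share at
   least 15% of the cloud. Without the guard, a scene whose floor is not
   in view would lose a slab through the person instead — the standalone
   `remove_floor_plane()` keeps the unconstrained contract (and empties a
   perfectly planar cloud), the pipeline uses the guarded variant.
3. **Lateral crop** at ± 1 m around the walkway axis by default. The crop
   bounds are scene geometry, not physics, so they are plain config.
4. **Centre-of-mass depth crop**: the mean `z` of the remaining points is
   taken to represent the person and everything farther than 0.5 m from it
   along the depth axis is dropped. The interval is closed: a point at
   exactly 50 cm stays.
5. **Rendering and normalization**: the cloud is rendered to a depth image
   and nonzero depths are mapped linearly to gray values, min depth → 1,
   max depth → 255 (a constant depth maps to 255). Mapping the minimum to
   1 rather than 0 keeps foreground unambiguous against the background 0.
   The per-image min–max range was chosen over a fixed sensor range; the
   mapped range is recorded so it can be inverted.
6. **Crop and scale**: the bounding box of all nonzero pixels is expanded
   symmetrically to a 3:4 window (zero-padded where it leaves the image)
   and resampled to 288 × 384 with nearest-neighbor interpolation —
   bilinear filtering would invent depths at silhouette edges. The window
   is constructed with an exactly 3:4 integer size so a single uniform
   scale factor applies; scale and offset form an invertible
   `crop_transform` (`original = model / scale + offset`), the record that
   later reconstructs original-image coordinates. On the model input size:
   sources describing this class of model print both "288 × 348" and
   "384 × 288"; since the aspect ratio is explicitly 3:4, 348 is treated
   as a typo for 384. The size is config-overridable.

`to_model_tensor()` replicates the gray image to 3 channels, scales to
[0, 1] and standardizes with the ImageNet channel statistics
(means 0.485/0.456/0.406, SDs 0.229/0.224/0.225) expected by
ResNet-backbone pose models.

## Heatmaps, loss and the predictor contract

Training targets are untruncated unit-peak Gaussians with σ = 1 px at each
visible keypoint's heatmap coordinate; occluded keypoints get all-zero
maps. The heatmap resolution is input/4 (72 × 96), the usual convention
for this model family. The training loss is the mean over *visible* joints
of half the mean squared pixel difference; values on occluded joints'
maps never enter it.

The package does not train a network. The predictor is a contract — ground
truth in heatmap coordinates in, a 17-map stack out — implemented by
`toy_predict()`: visible joints get a Gaussian bump at truth plus
isotropic pixel jitter with a peak amplitude drawn from a clipped-normal
visible-score distribution; occluded joints get a bump at a uniformly
random location with an amplitude from the occluded-score distribution.
Everything is seeded. The defaults (visible scores N(0.95, 0.03), occluded
N(0.45, 0.2), clipped to [0, 1]) were fixed once to give an operating
regime comparable to a well-trained detector — high separability with a
nonzero false-positive tail — and the tests compute their expectations
from these same clipped-normal tails (`pnorm`), not from tuned constants.
An actual training loop (optimizer, batch shuffling, model selection
across epochs) is deliberately out of scope; the harness contract is the
module boundary.

## Decoding and visibility

`decode_heatmaps()` takes the per-map argmax as the detection and the
maximum as its confidence; ties resolve row-major (smallest `v`, then
`u`), so a constant map decodes to (0, 0). Scores are raw heatmap maxima —
often called probabilities, but uncalibrated; they are not renormalized.

A keypoint is accepted as visible only if its score strictly surpasses a
threshold. The threshold is chosen per predictor (not per keypoint) from
the ROC curve of "predict visible when score > t" as the t minimizing the
distance `sqrt((1 - tpr)² + fpr²)` to the ideal corner; ties go to the
larger (more conservative) threshold. The curve includes the (0, 0) and
(1, 1) endpoints and its trapezoidal AUC equals the exhaustive pairwise
estimate, which the tests verify. Which split the scores come from is the
caller's choice — the selection function only sees (score, label) pairs.

`decode_heatmaps(refine = TRUE)` adds log-parabolic sub-pixel
interpolation through the peak's 4-neighborhood. For Gaussian-shaped peaks
the log-values are exactly quadratic, so the continuous peak is recovered
exactly; at map borders the integer argmax is kept. Plain argmax remains
the default — it is the documented decoding of the modeled system — but
refinement is what makes the noiseless end-to-end identity ("toy predictor
in, exactly the annotated pixels out, zero spatial error") achievable, and
the acceptance tests use it for that purpose: integer argmax alone cannot
beat the heatmap-grid quantization of ~2 original pixels.

## 3D localization

An accepted keypoint in original-image coordinates is placed in 3D by
reading the sensor depth at its rounded pixel and back-projecting;
positions are reported in cm. A sensor reading of zero means invalid: the
joint is excluded from spatial-error summaries, and the excluded fraction
is reported. The lookup deliberately uses the single rounded pixel with no
neighborhood pooling — pooling would contradict the premise that one zero
reading invalidates the joint. Reference 3D positions can come from the
generator (synthetic truth) or from annotated 2D plus the same depth
lookup; the second mode mirrors how reference positions are obtained on
real, annotation-only data, and is what the end-to-end tests use. Error
summaries report per-keypoint, per-axis medians with Tukey 1.5 × IQR
boxplot statistics.

## Evaluation suite

OKS weighs each visible keypoint's pixel error `d_i` against the person
scale `s` (root of the annotated silhouette area) and a per-keypoint
falloff `k_i = 2σ_i`, with the standard σ constants (nose 0.026, eyes
0.025, ears 0.035, shoulders 0.079, elbows 0.072, wrists 0.062, hips
0.107, knees 0.087, ankles 0.089). AP and AR average over the ten OKS
thresholds 0.50 : 0.05 : 0.95 (AP50/AP75 are the single-threshold
variants); AP uses 101-point interpolated precision; the medium/large
restrictions use the COCO pixel-area ranges (32²–96², > 96²), since no
alternative definition is available for this image size. Matching is
greedy per image in decreasing detection-score order, each detection
taking the unmatched annotation of highest OKS at or above the threshold;
annotations outside the evaluated area range are ignored rather than
counted, and a detection whose only match is ignored is itself ignored.
Although the intended use is single-person top-down (one detection per
image, where per-threshold precision is just the fraction of images at or
above the threshold), the general matcher is implemented and is checked
against an independent brute-force reference on random multi-detection
fixtures.

Visible/occluded classification is scored with confusion counts (visible
positive), precision/recall/F1, and per-joint sensitivity, specificity and
F1. Rates are kept at full precision; display rounding is 3 decimals with
R's round-half-even. Zero-denominator rates are `NA` and excluded from
aggregates rather than silently zeroed.

## The synthetic generator

The generator emulates the recording conditions the pipeline assumes — one
person 1–4.2 m from a knee-height 640 × 480 depth camera, standing on a
floor plane — not photorealism. The body is a set of capsules (cylinders
with spherical caps) around a 17-joint skeleton with configurable
anthropometry (default stature 1.75 m); capsules are the simplest shape
family that yields believable silhouettes and self-occlusion. Surface
points are sampled proportionally to capsule area (default 4000 per
person), the floor contributes uniform samples (default 8000), and sensor
noise is Gaussian along each viewing ray (default σ = 0.005 m, a
deliberately mild setting well inside the 2–4 cm error envelope of real
depth sensors, so unit tests measure the pipeline rather than the noise).
A joint is occluded when a capsule it does not belong to crosses its
camera ray in front of it — the annotator's notion of visibility — or when
it leaves the sensor frame, or when it is explicitly listed as occluded
(its surface neighborhood is then also removed). The silhouette polygon is
the convex hull of the projected person points, clipped to the image;
its area feeds OKS.

Walking sequences move the person along the depth axis with a sinusoidal
gait (cadence 0.9 cycles/s at 30 fps) and emit every 6th frame by default,
the 5 Hz sampling appropriate for still-image datasets. Dataset writing
splits scenes 70/15/15 with the test split holding *all* scenes of one
randomly chosen subject (leave-one-subject-out) and writes PLY clouds,
16-bit millimeter PNG depth images, COCO keypoint JSON and a manifest.
Pace variation is exposed (`cadence`, `swing`) but nothing downstream
depends on it.

What passing tests on these scenes does **not** show: robustness to real
sensor artifacts (speckle, edge shadows, material-dependent dropout),
loose clothing, annotation error, or multi-person scenes. The generator's
role is to make every contract testable with known ground truth, not to
certify field accuracy.

## Numerical choices and degenerate inputs

* Gray normalization of a constant-depth foreground maps to 255; an
  all-background image is an error, as is an empty cloud or a cloud of
  fewer than 3 points where a plane is required.
* The 50 cm depth crop is a closed interval; visibility filtering is a
  strict inequality ("surpass").
* RANSAC is seedable and bit-reproducible; the refit never runs on fewer
  than 3 inliers.
* The 16-bit PNG depth format quantizes to millimeters; depths above
  65.535 m are refused rather than wrapped.
* Heatmap Gaussians are evaluated on the whole map (no truncation); maps
  are small enough that the simplicity is worth the negligible cost.
* A peak outside the heatmap raises a clipped-peak warning but is still
  evaluated, so callers can decide.

## Problem sizes in the test suite

The suite fixes its own scales: default scenes use 4000 person + 8000
floor points; preprocessing-retention checks run 20 seeded scenes;
suite-vs-oracle equivalence runs 100 random fixtures of up to 5 images;
threshold-selection equivalence runs 100 seeded samples; the jittered
Monte-Carlo checks pool 10 scenes (about 170 joints). These sizes were
chosen so each statistical tolerance (stated next to the corresponding
test) is several sampling standard deviations wide.

## Known limitations

* The predictor is a contract with a toy implementation; no claims
  transfer to any specific trained network.
* OKS areas come from convex-hull silhouettes, which slightly overestimate
  concave poses.
* Spatial-error expectations for the depth axis are bounded (one capsule
  radius at the median under pixel jitter) rather than derived in closed
  form: a jittered pixel reads a different patch of a curved surface, and
  occasionally an adjacent body part, so the depth-error distribution is
  heavy-tailed by construction — the same reason the modeled system
  reports depth errors larger than lateral ones.
* Single person per scene throughout; the evaluation matcher handles
  multiple detections, but the generator does not produce multi-person
  scenes.
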