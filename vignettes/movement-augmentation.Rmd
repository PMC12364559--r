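---
title: "Quantifying movement and augmenting images for ecological object detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement and augmenting images for ecological object detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionaug)
library(dplyr)
```

## Motivation and model

Monitoring cameras — baited remote underwater video (BRUV), river
monitoring rigs, terrestrial camera traps — record *sequences*, yet the
detectors ecologists train on them consume single stills. Movement is
frequently the strongest cue separating a cryptic animal from its
background, and it lives entirely in the relation between neighbouring
frames. `motionaug` measures that movement per pixel and re-encodes it
inside the three colour channels a standard detector already accepts,
which keeps the approach detector-agnostic: when a better architecture
appears, the same augmented datasets feed it without modification.

All measures operate on frames normalised to `[0, 1]` (an `h × w × 3`
RGB array). For a frame of interest `F_t`:

**Absolute three-frame differencing.** The mean absolute difference to
the two neighbours at distance `Δt`, boosted by a scaling constant `υ`
and truncated to the colour range:

$$FD_a = \mathrm{clip}\Big(\upsilon \cdot \tfrac{1}{2}\big(|F_t - F_{t-\Delta t}| + |F_t - F_{t+\Delta t}|\big)\Big).$$

We deliberately do **not** threshold this to a binary moving/static
mask: kept continuous, the downstream detector learns from the training
labels which difference magnitudes matter.

**Directional differencing** keeps the sign of change, centred at 0.5 so
that it remains a displayable colour value:

$$FD_d = \mathrm{clip}\Big(\tfrac{1}{2} + \tfrac{\upsilon}{4}\big[(F_t - F_{t-\Delta t}) + (F_{t+\Delta t} - F_{t-\Delta t})\big]\Big).$$

Values above 0.5 mark channels increasing across the window, below 0.5
decreasing.

**Background subtraction via frame averaging.** A background estimate
averages out moving foreground across `n_b` historic frames spaced
`Δt_b` apart, and the frame of interest is scored by its signed distance
from it:

$$F_b = \tfrac{1}{n_b}\textstyle\sum_{i=1}^{n_b} F_{t-i\Delta t_b}, \qquad
BS_{FD} = \mathrm{clip}\Big(\tfrac{1}{2} + \tfrac{\upsilon}{2}(F_t - F_b)\Big).$$

**KNN foreground classification.** As the classical binary alternative,
each pixel keeps a buffer of its own values over the previous `history`
frames and is declared foreground when the majority of its `k` nearest
buffer samples (Euclidean distance in RGB) lie beyond `dist_threshold`.
This is a deliberately simplified, purely temporal reimplementation of
the KNN background-subtraction family: no spatial neighbourhoods, no
foreground resampling. Those refinements depend on undocumented
internals of existing implementations, and in comparative tuning the
continuous `BS_FD` measure is the stronger background-subtraction
predictor anyway, so the simple, fully specified classifier is kept as
the binary reference point. Defaults: `k = 3`, `history = 50`,
`dist_threshold = 0.08`.

**Optical flow.** The displacement field $(v_x, v_y)$ between `F_t` and
`F_{t+Δt}` with magnitude $r = \sqrt{v_x^2 + v_y^2}$ and direction
$\theta$. The printed closed form for direction is ambiguous about the
quadrant, so the package uses the two-argument arctangent
$\theta = \mathrm{atan2}(v_y, v_x)$ wrapped to $[0, 2\pi)$. Flow is
computed forward (`t → t+Δt`) by default — the backward comparison is a
flag — because the forward pair is already in the three-frame window
every other measure loads. The Farnebäck estimator is the usual choice
in practice and the adapter accepts it as a pluggable backend id, but no
dense-flow backend ships with the package; the built-in reference
estimator is exhaustive block matching (SSD over integer displacements
within `radius` on a luma block grid, bilinearly upsampled, ties broken
towards zero displacement so static input yields exactly zero flow).
Block matching is exact on rigid integer shifts — the property the tests
exploit — but it is blocky on deforming bodies and blind to sub-pixel
motion; it is a reference implementation, not a competitor to Farnebäck.

## From motion maps to augmented images

Detectors take three channels, so movement must displace or compress
colour:

* **all** — the image *is* the 3-layer motion map.
* **red** — the red layer is replaced by a single movement layer. Water
  absorbs long wavelengths first, so underwater frames carry little red
  signal; sacrificing that channel is nearly free in marine data. The
  3-layer differencing maps collapse to one layer by averaging the three
  layers; flow contributes its magnitude layer; the KNN mask is already
  single-layer.
* **pca** — green and blue carry a 2-component PCA compression of the
  original colours and red carries movement, retaining (compressed)
  colour alongside motion. Pixels from `n_t` sampled training frames are
  stacked into an `(h·w·n_t) × 3` matrix (each row a pixel, each column
  a colour), the top two principal directions are taken, and scores are
  whitened to unit variance. Default `n_t = min(all, 500)`, sampled
  without replacement under the stated seed.

Whitened scores are unbounded, but augmented images must be valid colour
data, so the model includes an affine range map fitted so that 99.5% of
the sampled whitened scores land in `[0, 1]` (the 0.25% tails clip).
How unbounded whitened values become storable image data is a genuine
design choice — nothing in the method pins it down — and the affine map
was chosen because it is invertible, cheap, and recorded bit-exactly in
the model JSON, so the transform any dataset was built with can always
be reproduced. Eigenvector signs are arbitrary, so each component is
oriented with its largest-magnitude coefficient positive to make fits
reproducible. A pixel cloud with variance in fewer than two directions
(pure grey training data is the canonical case) gets whitening scale 0
for the degenerate component with a warning; fully constant input is an
error.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `Δt` (frames) | neighbour distance for differencing/flow | 1 | larger values accentuate slow motion, with less spatial precision; video data tends to want larger `Δt` (4–5) than burst data (1) |
| `υ` (unitless) | difference scaling | 1 | boosts faint motion before truncation; 1 and 15 bracket the useful range in practice |
| `n_b`, `Δt_b` | background frame count / spacing | 10, 1 | more, wider-spaced frames average foreground out better when long sequences exist (spacings of 100+ frames work for video) |
| `mode` | all / red / pca | all | red/pca preserve some colour; underwater data loses least to `red` |
| `r_max` | flow magnitude mapped to 1.0 | 99th percentile of `r` | percentile rather than max to resist single-pixel flow outliers; no normalisation is prescribed by the method itself |

Tuning selects among these on the *validation* split only
(`select_best()` records `splits_consulted = "val"` so the guarantee is
auditable); the test split is reserved for final comparisons
(`report_tuning()`). The default is single-stage argmax; `two_stage =
TRUE` mirrors the workflow of tuning motion parameters first (at a fixed
mode) and then choosing the augmentation mode with those parameters
frozen — cheaper when each grid point costs a detector training run.
Exact ties break towards the simpler configuration (smaller `Δt`, then
smaller `υ`, then mode order all < red < pca).

## Boundary policy and numerical choices

The first and last `Δt` frames of a sequence have no neighbour on one
side, and early frames lack background history. The default policy
clamps to the nearest existing frame, so *every* labelled frame can be
augmented (a labelled frame is too valuable to drop); `boundary =
"strict"` errors instead, and the dataset run log records which images
were clamped. Clipping to `[0, 1]` is applied after scaling for all
three differencing measures — including the centred ones, which leave
the range whenever `υ > 1` — because the output must remain a valid
image.

Other fixed conventions: boxes are stored centre-normalised (YOLO) and
convert to 0-based, half-open pixel corners (`width = x2 − x1`), which
makes IOU arithmetic exact on integers; image resampling is bilinear
with pixel centres at half-integer positions and edge clamping, under
which a 2× downsample averages 2×2 blocks exactly; motion maps persist
as 8-bit PNG (the portable, lossless container available everywhere)
plus a JSON sidecar carrying method and parameters at full precision —
the 1/255 quantisation is documented and the sidecar, not the pixels,
is the provenance record. Video containers are not decoded directly:
codecs are not bit-stable across platforms, so the canonical input is a
numbered PNG/JPEG burst folder (decode video with an external tool
first); passing a video file raises an explicit capability error.

## Evaluation

Detections are matched greedily in descending score order; a detection
is a true positive when its best-IOU unmatched same-class ground-truth
box on the same image reaches the threshold (IOU ties break by
ground-truth input order, score ties by detection input order — both
documented so results are reproducible). AP is the area under the
all-point interpolated precision–recall curve, the PASCAL convention;
`mAP@τ` averages AP over classes with at least one ground-truth box,
and `mAP@50:95` averages the ten thresholds 0.50–0.95. The widely
printed precision formula "TP/(TP+TN)" is a typo for the standard
TP/(TP+FP), which is what the package computes. Classes with ground
truth but no detections contribute AP 0; detections for classes with no
ground truth are logged and excluded so they cannot distort the mean.
The test suite pins the implementation to an independent evaluator that
enumerates every score cutoff and recomputes precision/recall from
scratch on 1,000 random small instances.

## What the synthetic scenes do and do not show

`scene_spec()`/`generate_sequence()` render uniform, gradient or
textured backgrounds, rectangle/ellipse objects on exact per-frame
integer trajectories (per-frame rather than parametric so tests can
assert box positions to the pixel), underwater red suppression (red
channel scaled by a factor in `[0, 0.2]`), monochrome night frames
(R=G=B luma, BT.601 weights 0.299/0.587/0.114) and i.i.d. Gaussian
pixel noise added after rendering and clipped. Ground-truth boxes are
recomputed from the rendered mask, so their IOU with the rendered
object is exactly 1. Noise defaults are free choices — published
monitoring datasets do not come with noise characterisations — and a
per-pixel σ of 0.01–0.02 was fixed once as a plausible sensor-noise
scale.

These scenes exercise the *arithmetic* of every measure and the
plumbing of the whole pipeline (determinism, label invariance, leakage
guards). They do not contain camera motion, illumination change,
compression artefacts, schooling or occlusion, so green tests here say
nothing about detection accuracy on real footage — that question needs
a trained detector on real data, which is exactly the external step the
tuning workflow delegates.

```{r example}
spec <- scene_spec(
  height = 64, width = 64, n_frames = 5, background = "uniform",
  noise_sd = 0.01,
  objects = list(object_spec(size = c(12, 12), position = c(10, 26),
                             contrast = 0.4, trajectory = c(3, 0))),
  seed = 1
)
out <- generate_sequence(spec)
m <- frame_difference_abs(out$sequence, t = 3, delta_t = 1, upsilon = 1)
autoplot(collapse_layers(m))
```

## Problem sizes used in the checks

The package's checks run at deliberately small scale, chosen as the
smallest sizes at which every property is non-trivial: 8×8×3 sequences
for the oracle-equivalence loops (100+ random sequences), 64×64 scenes
for motion recovery (20 seeds), ≤10 boxes and ≤3 classes per instance
for the 1,000-instance mAP comparison, and a 12–20 image dataset for
end-to-end determinism. All quantities are exact identities or
agreements to 1e-9–1e-12, so scale adds nothing but time.

## Known limitations

* Block-matching flow is integer-valued and grid-smoothed; sub-pixel or
  non-rigid motion needs an external dense-flow backend via the adapter.
* The KNN classifier is per-pixel and purely temporal, a reference
  simplification of production background subtractors.
* 8-bit PNG persistence quantises motion maps to 1/255; the in-memory
  pipeline is full double precision.
* Augmented copies of a dataset must be regenerated for *prediction*
  inputs too — a detector trained on movement-augmented images expects
  the same augmentation at inference time.
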