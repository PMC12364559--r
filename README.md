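# motionaug

Movement-based image augmentation for ecological object detection.

## The problem

Ecologists increasingly hand camera-trap bursts and underwater monitoring
video to off-the-shelf object detectors (YOLO-family models and similar),
but those detectors see one still at a time. Cryptic animals — a
camouflaged fish over a reef, a wallaby at night — are often easiest to
find by what *moves*, information a still image throws away. Changing the
detector's architecture to accept extra movement channels ties the whole
pipeline to one model; `motionaug` instead quantifies movement per pixel
and folds it back into the three RGB channels of ordinary images, so any
current or future detector can be trained on movement-augmented data
unchanged.

## What it computes

For a frame of interest `F_t` in a sequence (values normalised to
`[0, 1]`), with neighbour distance `Δt` in frames and scaling constant
`υ`:

* **Absolute three-frame difference**
  `FD_a = clip( υ · ½ ( |F_t − F_{t−Δt}| + |F_t − F_{t+Δt}| ) )` —
  0 where nothing changes, larger where colour values change in either
  direction.
* **Directional three-frame difference**
  `FD_d = clip( ½ + (υ/4) [ (F_t − F_{t−Δt}) + (F_{t+Δt} − F_{t−Δt}) ] )`
  — centred at 0.5; above 0.5 the channel is increasing across the
  window, below it decreasing.
* **Background subtraction via frame averaging**
  `F_b = (1/n_b) Σ_{i=1..n_b} F_{t−iΔt_b}`, then
  `BS_FD = clip( ½ + (υ/2)(F_t − F_b) )` — a continuous
  foreground/background score rather than a thresholded mask.
* **KNN foreground mask** — a per-pixel K-nearest-neighbour classifier
  over each pixel's own history buffer (binary output).
* **Dense optical flow** — per-pixel displacement `(vx, vy)` with
  magnitude `r = √(vx² + vy²)` and direction `θ = atan2(vy, vx)`,
  estimated by a built-in exhaustive block-matching reference estimator
  (the adapter is pluggable for external dense-flow backends), encodable
  as a single magnitude layer or an HSV direction/magnitude image.

Three augmentation modes turn a motion map plus the original frame into
a valid 3-channel image: **all** (image replaced by the 3-layer motion
map), **red** (red channel — largely empty underwater — replaced by a
single movement layer) and **pca** (green/blue carry a whitened 2-component
PCA compression of the original colours, red carries movement).

Around the core sit a synthetic scene generator with exact ground-truth
boxes, YOLO-format dataset I/O, PASCAL-style mAP evaluation
(all-point-interpolated AP at IOU 0.50, 0.75 and 0.50:0.95), and a
tuning workflow that expands a parameter grid, selects the best
configuration per method on the *validation* split only, and reports
test-split comparisons.

## Worked example

```r
library(motionaug)

# A 64x64 synthetic scene: one 12x12 square moving 3 px/frame rightward.
spec <- scene_spec(
  height = 64, width = 64, n_frames = 5, background = "uniform",
  noise_sd = 0.01,
  objects = list(object_spec(size = c(12, 12), position = c(10, 26),
                             contrast = 0.4, trajectory = c(3, 0))),
  seed = 1
)
out <- generate_sequence(spec)

m <- frame_difference_abs(out$sequence, t = 3, delta_t = 1, upsilon = 1)
range(m$values)
#> [1] 0.0000000 0.2372549

aug <- augment_replace_red(get_frame(out$sequence, 3), collapse_layers(m))
aug
#> <augmented_image> mode red, motion fd_a

gt  <- dplyr::filter(out$annotations, image_ref == "f000003")
det <- dplyr::mutate(gt, score = 0.9)
glance(map_suite(det, gt))
#> # A tibble: 1 x 3
#>   map50 map75 map50_95
#>   <dbl> <dbl>    <dbl>
#> 1     1     1        1
```

The differencing map peaks at ~0.24 on the leading and trailing edges
of the motion: with a 3 px step, each edge pixel differs from only one
of its two neighbour frames, so `FD_a` reaches half the square's 0.4
contrast (plus a little noise). A detection equal to the ground-truth
box scores mAP 1.0 at every IOU threshold.

A thin CLI mirrors the library (`inst/cli/motionaug`): subcommands
`simulate`, `motion`, `fit-pca`, `augment`, `eval`, `tune`, `report`.

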