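# Shared fixture builders (all generated in code; nothing on disk).

# 1x1x3 sequence from per-frame scalar values (all channels equal).
scalar_seq <- function(values) {
  frame_sequence(lapply(values, function(v) array(v, dim = c(1, 1, 3))))
}

# Random sequence of n h x w x 3 frames, values on the 8-bit grid.
random_seq <- function(n = 5, h = 8, w = 8, seed = 1) {
  set.seed(seed)
  frame_sequence(lapply(seq_len(n), function(i) {
    array(round(runif(h * w * 3) * 255) / 255, dim = c(h, w, 3))
  }))
}

# Pair of textured frames where the second is the first rigidly shifted
# `shift` pixels to the right (positive vx under forward flow).
rigid_shift_pair <- function(h = 32, w = 48, shift = 3, seed = 5) {
  set.seed(seed)
  wide <- matrix(runif(h * (w + 2 * abs(shift))), h, w + 2 * abs(shift))
  off <- abs(shift)
  a <- wide[, (off + 1):(off + w)]
  b <- wide[, (off + 1 - shift):(off + w - shift)]  # b(x) = a(x - shift)
  list(
    a = array(rep(a, 3), dim = c(h, w, 3)),
    b = array(rep(b, 3), dim = c(h, w, 3))
  )
}

# Grey frames (R=G=B) with varying intensity: rank-1 pixel cloud.
grey_frames <- function(n = 5) {
  lapply(seq(0.1, 0.9, length.out = n), function(v) {
    y <- v + outer(seq(-0.05, 0.05, length.out = 8), rep(1, 8))
    array(rep(y, 3), dim = c(8, 8, 3))
  })
}

# Moving-square scene used by the motion-recovery checks.
recovery_scene <- function(seed, noise_sd = 0.01, contrast = 0.4) {
  scene_spec(
    height = 64, width = 64, n_frames = 5,
    background = "uniform", noise_sd = noise_sd,
    objects = list(object_spec(
      size = c(12, 12), position = c(10, 26),
      contrast = contrast, trajectory = c(3, 0)
    )),
    seed = seed
  )
}

# Tight box (normalised, corner form) of a logical mask.
mask_box <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) {
    return(NULL)
  }
  c((min(cols) - 1) / w, (min(rows) - 1) / h, max(cols) / w, max(rows) / h)
}

# Union of ground-truth corner boxes (annotation tibble rows).
union_box <- function(ann) {
  x1 <- min(ann$cx - ann$bw / 2)
  y1 <- min(ann$cy - ann$bh / 2)
  x2 <- max(ann$cx + ann$bw / 2)
  y2 <- max(ann$cy + ann$bh / 2)
  c(x1, y1, x2, y2)
}

# Recovery IOU of thresholded collapsed FD_a against the ground-truth
# union over the differencing window, for one seeded scene.
fd_recovery_iou <- function(seed, threshold = 0.1, delta_t = 1, t = 3) {
  out <- generate_sequence(recovery_scene(seed))
  m <- collapse_layers(frame_difference_abs(out$sequence, t, delta_t, 1))
  box <- mask_box(m$values[, , 1] > threshold)
  gt <- dplyr::filter(
    out$annotations,
    image_ref %in% sprintf("f%06d", c(t - delta_t, t, t + delta_t))
  )
  iou(box, union_box(gt))
}

# Random small detection/ground-truth instance for the mAP oracle checks.
# Scores are continuous, so ties have probability zero and the
# cutoff-enumeration oracle is exactly comparable.
random_eval_instance <- function(seed, max_boxes = 10, max_classes = 3) {
  set.seed(seed)
  n_img <- sample(1:3, 1)
  n_cls <- sample(1:max_classes, 1)
  n_gt <- sample(1:max_boxes, 1)
  n_det <- sample(0:max_boxes, 1)
  rand_boxes <- function(n, detection) {
    if (n == 0 && detection) {
      return(tibble::tibble(
        image_ref = character(), class_id = integer(),
        cx = double(), cy = double(), bw = double(), bh = double(),
        score = double()
      ))
    }
    cx <- runif(n, 0.2, 0.8)
    cy <- runif(n, 0.2, 0.8)
    out <- tibble::tibble(
      image_ref = sample(sprintf("img%d", 1:n_img), n, replace = TRUE),
      class_id = sample(0:(n_cls - 1), n, replace = TRUE),
      cx = cx, cy = cy,
      bw = runif(n, 0.05, 0.3), bh = runif(n, 0.05, 0.3)
    )
    if (detection) out$score <- runif(n)
    out
  }
  gts <- rand_boxes(n_gt, detection = FALSE)
  # Mix of perturbed copies of ground truth (matchable) and noise boxes.
  n_copy <- min(n_det, n_gt)
  dets <- rand_boxes(n_det, detection = TRUE)
  if (n_copy > 0) {
    jit <- gts[sample(n_gt, n_copy), ]
    jit$cx <- pmin(pmax(jit$cx + runif(n_copy, -0.05, 0.05), 0.15), 0.85)
    jit$cy <- pmin(pmax(jit$cy + runif(n_copy, -0.05, 0.05), 0.15), 0.85)
    jit$score <- runif(n_copy)
    dets[seq_len(n_copy), ] <- jit
  }
  list(dets = dets, gts = gts)
}
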