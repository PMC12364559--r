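#' Dense optical flow between two frames
#'
#' Estimates the per-pixel displacement field between frame `t` and frame
#' `t + delta_t` (forward flow; set `direction = "backward"` to compare
#' `t - delta_t -> t`). The estimator is pluggable:
#'
#' * `"block_match"` — the built-in reference implementation: exhaustive
#'   sum-of-squared-differences search over integer displacements within
#'   `radius`, on luma blocks of size `block` centred on a regular grid
#'   with spacing `step`, bilinearly upsampled to full resolution. Ties in
#'   SSD are broken towards the smallest displacement (zero first), then
#'   by scan order, so a static pair yields exactly zero flow.
#' * `"farneback"` — delegated to an external dense-flow backend; no such
#'   backend is available to this package, so requesting it raises a
#'   capability error. The adapter keeps the interface so a backend can
#'   be plugged in where one exists.
#'
#' @inheritParams frame_difference_abs
#' @param estimator `"block_match"` or `"farneback"`.
#' @param direction `"forward"` (`t -> t + delta_t`) or `"backward"`.
#' @param radius Maximum displacement searched, pixels.
#' @param block Block side length, pixels.
#' @param step Grid spacing between block centres, pixels.
#'
#' @return A `flow_field` object: `h x w` matrices `vx`, `vy` (pixel
#'   displacement per `delta_t` frames) plus derived magnitude `r =
#'   sqrt(vx^2 + vy^2)` and direction `theta = atan2(vy, vx)` wrapped to
#'   `[0, 2*pi)`.
#' @export
#' @examples
#' sc <- scene_spec(background = "textured",
#'                  objects = list(object_spec(trajectory = c(2, 0))))
#' fs <- generate_sequence(sc)$sequence
#' fl <- flow_field(fs, t = 2, radius = 3)
#' median(fl$vx)
flow_field <- function(seq, t, delta_t = 1,
                       estimator = c("block_match", "farneback"),
                       direction = c("forward", "backward"),
                       radius = 4, block = 8, step = 4,
                       boundary = c("clamp", "strict")) {
  estimator <- match.arg(estimator)
  direction <- match.arg(direction)
  boundary <- match.arg(boundary)
  if (estimator == "farneback") {
    abort(
      "estimator 'farneback' requires an external dense-flow backend, which is not available; use estimator = 'block_match'.",
      class = "motionaug_capability_error"
    )
  }
  if (direction == "forward") {
    a <- get_frame(seq, t, boundary)
    b <- get_frame(seq, t + delta_t, boundary)
  } else {
    a <- get_frame(seq, t - delta_t, boundary)
    b <- get_frame(seq, t, boundary)
  }
  bm <- block_match_flow(luma(a), luma(b), radius = radius,
                         block = block, step = step)
  r <- sqrt(bm$vx^2 + bm$vy^2)
  theta <- atan2(bm$vy, bm$vx) %% (2 * pi)
  structure(
    list(vx = bm$vx, vy = bm$vy, r = r, theta = theta,
         params = list(delta_t = delta_t, estimator = estimator,
                       direction = direction, radius = radius,
                       block = block, step = step, t = t)),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %dx%d, estimator %s, median |v| = %.2f px\n",
    nrow(x$vx), ncol(x$vx), x$params$estimator, median(x$r)
  ))
  invisible(x)
}

# Exhaustive SSD block matching on luma matrices a -> b.  Returns vx, vy
# at full resolution (grid estimates bilinearly upsampled).
block_match_flow <- function(a, b, radius, block, step) {
  h <- nrow(a)
  w <- ncol(a)
  half <- block %/% 2
  cys <- unique(pmin(pmax(seq(1 + half, h - half + (block %% 2 == 0), by = step),
                          1 + half), h - half + (block %% 2 == 0)))
  cxs <- unique(pmin(pmax(seq(1 + half, w - half + (block %% 2 == 0), by = step),
                          1 + half), w - half + (block %% 2 == 0)))
  if (length(cys) == 0) cys <- max(1, h %/% 2)
  if (length(cxs) == 0) cxs <- max(1, w %/% 2)
  gvx <- matrix(0, length(cys), length(cxs))
  gvy <- matrix(0, length(cys), length(cxs))
  # Candidate displacements ordered by |d| then scan order, so the first
  # strict improvement wins and zero displacement is the tie-break.
  cand <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dy, cand$dx), ]
  for (iy in seq_along(cys)) {
    for (ix in seq_along(cxs)) {
      cy <- cys[iy]
      cx <- cxs[ix]
      y1 <- max(1, cy - half)
      y2 <- min(h, cy + half - (block %% 2 == 0))
      x1 <- max(1, cx - half)
      x2 <- min(w, cx + half - (block %% 2 == 0))
      ref <- a[y1:y2, x1:x2]
      best <- Inf
      bdx <- 0
      bdy <- 0
      for (j in seq_len(nrow(cand))) {
        dx <- cand$dx[j]
        dy <- cand$dy[j]
        yy1 <- y1 + dy
        yy2 <- y2 + dy
        xx1 <- x1 + dx
        xx2 <- x2 + dx
        if (yy1 < 1 || xx1 < 1 || yy2 > h || xx2 > w) next
        ssd <- sum((ref - b[yy1:yy2, xx1:xx2])^2)
        if (ssd < best - 1e-12) {
          best <- ssd
          bdx <- dx
          bdy <- dy
        }
      }
      gvx[iy, ix] <- bdx
      gvy[iy, ix] <- bdy
    }
  }
  list(
    vx = bilinear_resample(gvx, h, w),
    vy = bilinear_resample(gvy, h, w)
  )
}

#' Encode a flow field as motion-map layers
#'
#' `"magnitude1"` keeps only the magnitude of flow, dropping direction: a
#' single layer `clip(r / r_max)`. `"hsv3"` encodes direction as hue and
#' normalised magnitude as value (full saturation), converted to RGB — the
#' familiar dense-flow visualisation, usable as a 3-layer augmentation.
#'
#' @param flow A [flow_field()].
#' @param mode `"magnitude1"` or `"hsv3"`.
#' @param r_max Magnitude mapped to 1.0. `NULL` uses the 99th percentile
#'   of `r` over the frame (robust to flow outliers); if that is 0 (static
#'   frame) the map is all zeros.
#' @return A [motion_map()].
#' @export
flow_to_layers <- function(flow, mode = c("magnitude1", "hsv3"),
                           r_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(flow, "flow_field"))
  if (is.null(r_max)) {
    r_max <- as.numeric(quantile(flow$r, 0.99))
  }
  if (r_max < 0 || (r_max == 0 && any(flow$r > 0))) {
    abort("`r_max` must be > 0.")
  }
  rn <- if (r_max > 0) clamp01(flow$r / r_max) else flow$r * 0
  params <- c(flow$params, list(r_max = r_max, mode = mode))
  if (mode == "magnitude1") {
    return(motion_map(rn, "flow", params))
  }
  hdeg <- flow$theta * 180 / pi
  rgb <- hsv_to_rgb(as.vector(hdeg), rep(1, length(hdeg)), as.vector(rn))
  vals <- array(c(rgb$r, rgb$g, rgb$b), dim = c(dim(flow$vx), 3L))
  motion_map(vals, "flow", params)
}
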