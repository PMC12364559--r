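#' Specify a synthetic monitoring scene
#'
#' The scene generator renders frame sequences with known ground-truth
#' boxes so the whole motion/augmentation/evaluation stack is testable
#' without any real footage. It emulates the regimes seen in ecological
#' monitoring data: static or slowly drifting backgrounds, one or more
#' moving objects, underwater colour casts (suppressed red channel),
#' monochrome night frames and per-pixel sensor noise.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames (>= 3 so a three-frame difference is
#'   always possible).
#' @param background One of `"uniform"`, `"gradient"` (horizontal
#'   luminance ramp) or `"textured"` (seeded smooth random field).
#' @param colour_cast `"none"`, `"underwater"` (red channel multiplied by
#'   `red_factor`) or `"monochrome"` (R=G=B luma).
#' @param red_factor Red-channel attenuation for the underwater cast, in
#'   `[0, 0.2]`.
#' @param noise_sd Per-pixel i.i.d. Gaussian noise sd in `[0, 0.2]` ([0,1]
#'   units), added after rendering and then clipped.
#' @param objects List of [object_spec()]s.
#' @param seed Integer seed; the generator is bit-deterministic given it.
#'
#' @return A `scene_spec` list.
#' @seealso [generate_sequence()]
#' @export
scene_spec <- function(height = 64, width = 64, n_frames = 5,
                       background = c("uniform", "gradient", "textured"),
                       colour_cast = c("none", "underwater", "monochrome"),
                       red_factor = 0.1, noise_sd = 0,
                       objects = list(), seed = 1L) {
  background <- match.arg(background)
  colour_cast <- match.arg(colour_cast)
  if (!is_count(n_frames, min = 3L)) {
    abort("`n_frames` must be an integer >= 3.")
  }
  if (noise_sd < 0 || noise_sd > 0.2) {
    abort("`noise_sd` must lie in [0, 0.2].")
  }
  if (red_factor < 0 || red_factor > 0.2) {
    abort("`red_factor` must lie in [0, 0.2].")
  }
  spec <- structure(
    list(
      height = as.integer(height), width = as.integer(width),
      n_frames = as.integer(n_frames), background = background,
      colour_cast = colour_cast, red_factor = red_factor,
      noise_sd = noise_sd, objects = objects, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

#' Specify a moving object within a scene
#'
#' @param size `c(width, height)` of the object in pixels.
#' @param position `c(x, y)` top-left pixel (1-based) at the first frame.
#' @param colour RGB triple in `[0, 1]`, or `NULL` to derive a colour from
#'   `contrast` against the background mean.
#' @param contrast Absolute mean difference from the background in `[0,1]`
#'   units; used to derive `colour` when it is `NULL`.
#' @param trajectory Per-frame displacement in pixels/frame: either a
#'   single `c(dx, dy)` applied every frame, or an `(n_frames - 1) x 2`
#'   matrix of integer displacements. Per-frame (not parametric) so tests
#'   can assert exact box positions.
#' @param shape `"rectangle"` or `"ellipse"`.
#'
#' @return An `object_spec` list.
#' @export
object_spec <- function(size = c(10, 10), position = c(1, 1),
                        colour = NULL, contrast = 0.5,
                        trajectory = c(0, 0),
                        shape = c("rectangle", "ellipse")) {
  shape <- match.arg(shape)
  if (contrast < 0) {
    abort("`contrast` must be >= 0.")
  }
  if (is.numeric(trajectory) && is.null(dim(trajectory))) {
    trajectory <- matrix(trajectory, ncol = 2)
  }
  structure(
    list(
      size = as.integer(size), position = as.integer(position),
      colour = colour, contrast = contrast,
      trajectory = trajectory, shape = shape
    ),
    class = "object_spec"
  )
}

# Per-frame integer top-left positions from the trajectory, recycling a
# single displacement row across all steps.
object_positions <- function(obj, n_frames) {
  steps <- obj$trajectory
  if (nrow(steps) == 1L) {
    steps <- steps[rep(1L, n_frames - 1L), , drop = FALSE]
  }
  if (nrow(steps) < n_frames - 1L) {
    abort("object trajectory must define a displacement for every frame.")
  }
  pos <- matrix(0L, n_frames, 2)
  pos[1, ] <- obj$position
  for (t in seq_len(n_frames - 1L)) {
    pos[t + 1L, ] <- pos[t, ] + round(steps[t, ])
  }
  pos
}

validate_scene_spec <- function(spec) {
  for (k in seq_along(spec$objects)) {
    obj <- spec$objects[[k]]
    pos <- object_positions(obj, spec$n_frames)
    x2 <- pos[, 1] + obj$size[1] - 1L
    y2 <- pos[, 2] + obj$size[2] - 1L
    if (any(pos[, 1] < 1L) || any(pos[, 2] < 1L) ||
        any(x2 > spec$width) || any(y2 > spec$height)) {
      t_bad <- which(pos[, 1] < 1L | pos[, 2] < 1L |
                       x2 > spec$width | y2 > spec$height)[1]
      abort(sprintf(
        "object %d leaves the %dx%d frame at frame %d.",
        k, spec$width, spec$height, t_bad
      ), class = "motionaug_bounds_error")
    }
  }
  invisible(spec)
}

render_background <- function(spec) {
  h <- spec$height
  w <- spec$width
  switch(spec$background,
    uniform = array(0.35, dim = c(h, w, 3)),
    gradient = {
      ramp <- matrix(seq(0.2, 0.6, length.out = w), h, w, byrow = TRUE)
      array(rep(ramp, 3), dim = c(h, w, 3))
    },
    textured = {
      # Smooth seeded random field: coarse uniform grid upsampled
      # bilinearly, so neighbouring pixels correlate like vegetation or
      # sediment texture does.
      coarse_h <- max(2L, h %/% 8L)
      coarse_w <- max(2L, w %/% 8L)
      out <- array(0, dim = c(h, w, 3))
      base <- matrix(runif(coarse_h * coarse_w, 0.15, 0.65),
                     coarse_h, coarse_w)
      for (ch in 1:3) {
        jitter <- matrix(runif(coarse_h * coarse_w, -0.05, 0.05),
                         coarse_h, coarse_w)
        out[, , ch] <- bilinear_resample(base + jitter, h, w)
      }
      clamp01(out)
    }
  )
}

object_colour <- function(obj, bg_mean) {
  if (!is.null(obj$colour)) {
    return(obj$colour)
  }
  up <- bg_mean + obj$contrast
  if (all(up <= 1)) clamp01(up) else clamp01(bg_mean - obj$contrast)
}

# Pixel mask of an object at a given top-left position; TRUE where the
# object covers the pixel.
object_mask <- function(obj, pos, h, w) {
  mask <- matrix(FALSE, h, w)
  x1 <- pos[1]
  y1 <- pos[2]
  x2 <- x1 + obj$size[1] - 1L
  y2 <- y1 + obj$size[2] - 1L
  if (obj$shape == "rectangle") {
    mask[y1:y2, x1:x2] <- TRUE
  } else {
    cx <- (x1 + x2) / 2
    cy <- (y1 + y2) / 2
    a <- obj$size[1] / 2
    b <- obj$size[2] / 2
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  }
  mask
}

#' Generate a synthetic frame sequence with exact ground-truth boxes
#'
#' Renders the scene frame by frame: background, then each object at its
#' trajectory position, then the colour cast, then additive Gaussian
#' noise (clipped to `[0, 1]`). Ground-truth boxes are recomputed from the
#' rendered object mask, so they bound the object pixels exactly; frames
#' are quantised to the 8-bit grid so that writing and re-reading PNGs is
#' lossless.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `sequence` (a [frame_sequence()]) and
#'   `annotations` (tibble of per-frame ground truth with `image_ref` =
#'   `f%06d`, `class_id` = object index - 1).
#' @export
#' @examples
#' sc <- scene_spec(objects = list(object_spec(trajectory = c(2, 0))))
#' out <- generate_sequence(sc)
#' out$annotations
generate_sequence <- function(spec) {
  validate_scene_spec(spec)
  h <- spec$height
  w <- spec$width
  with_preserved_seed(spec$seed, {
    bg <- render_background(spec)
    bg_mean <- apply(bg, 3, mean)
    frames <- vector("list", spec$n_frames)
    anns <- vector("list", spec$n_frames)
    positions <- lapply(spec$objects, object_positions, n_frames = spec$n_frames)
    for (t in seq_len(spec$n_frames)) {
      frame <- bg
      boxes <- list()
      for (k in seq_along(spec$objects)) {
        obj <- spec$objects[[k]]
        mask <- object_mask(obj, positions[[k]][t, ], h, w)
        col <- object_colour(obj, bg_mean)
        for (ch in 1:3) {
          layer <- frame[, , ch]
          layer[mask] <- col[ch]
          frame[, , ch] <- layer
        }
        # Exact bounding box from the rendered mask (0-based, half-open).
        rows <- range(which(rowSums(mask) > 0))
        cols <- range(which(colSums(mask) > 0))
        x1 <- cols[1] - 1L
        x2 <- cols[2]
        y1 <- rows[1] - 1L
        y2 <- rows[2]
        boxes[[k]] <- tibble::tibble(
          image_ref = sprintf("f%06d", t),
          class_id = k - 1L,
          cx = (x1 + x2) / 2 / w, cy = (y1 + y2) / 2 / h,
          bw = (x2 - x1) / w, bh = (y2 - y1) / h
        )
      }
      frame <- apply_colour_cast(frame, spec)
      if (spec$noise_sd > 0) {
        frame <- frame + array(rnorm(h * w * 3, sd = spec$noise_sd),
                               dim = c(h, w, 3))
      }
      # Quantise to the 8-bit grid: PNG round trips become bit-identical.
      frames[[t]] <- round(clamp01(frame) * 255) / 255
      anns[[t]] <- if (length(boxes)) dplyr::bind_rows(boxes) else
        empty_annotations()
    }
    list(
      sequence = frame_sequence(frames, source_id = sprintf("scene%d", spec$seed)),
      annotations = dplyr::bind_rows(anns)
    )
  })
}

apply_colour_cast <- function(frame, spec) {
  switch(spec$colour_cast,
    none = frame,
    underwater = {
      frame[, , 1] <- frame[, , 1] * spec$red_factor
      frame
    },
    monochrome = {
      y <- luma(frame)
      array(rep(y, 3), dim = dim(frame))
    }
  )
}

#' Collapse a sequence to monochrome night frames
#'
#' Replaces every channel with the frame's luma (BT.601 weights 0.299,
#' 0.587, 0.114), emulating infrared night shots where R=G=B. Grey input
#' is unchanged.
#'
#' @param seq A [frame_sequence()].
#' @return A [frame_sequence()] with R=G=B per pixel.
#' @export
render_monochrome <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  seq$frames <- lapply(seq$frames, function(f) {
    y <- luma(f)
    array(rep(y, 3), dim = dim(f))
  })
  seq
}

#' Write a synthetic scene as an on-disk labelled dataset
#'
#' Materialises [generate_sequence()] output in the layout the real-data
#' pipeline reads: a numbered PNG folder per sequence, one YOLO label file
#' per labelled frame, and a manifest YAML linking each labelled image to
#' its frame position and split.
#'
#' @param spec A [scene_spec()].
#' @param dir Output dataset root.
#' @param split Split assigned to every labelled frame (or a vector
#'   recycled across frames).
#' @param classes Class-name table; defaults to `obj<k>` per object.
#' @return The manifest list, invisibly readable back via
#'   [read_manifest()].
#' @export
write_scene_dataset <- function(spec, dir, split = "train", classes = NULL) {
  out <- generate_sequence(spec)
  seq_name <- out$sequence$source_id
  dir.create(file.path(dir, "sequences", seq_name),
             recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  write_sequence(out$sequence, file.path(dir, "sequences", seq_name))
  n <- n_frames(out$sequence)
  ids <- sprintf("%s_f%06d", seq_name, seq_len(n))
  split <- rep_len(split, n)
  for (t in seq_len(n)) {
    ann <- dplyr::filter(out$annotations,
                         .data$image_ref == sprintf("f%06d", t))
    write_annotations(ann, file.path(dir, "labels", paste0(ids[t], ".txt")))
  }
  classes <- classes %||%
    sprintf("obj%d", seq_len(max(1L, length(spec$objects))))
  manifest <- list(
    root = dir,
    classes = classes,
    entries = tibble::tibble(
      image = ids, sequence = seq_name,
      frame = seq_len(n), split = split
    )
  )
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
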