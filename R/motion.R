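#' Motion maps
#'
#' A `motion_map` holds a per-pixel movement measure: an `h x w x L` array
#' (`L` 1 or 3) of values in `[0, 1]`, together with the method that
#' produced it and its parameters, so every augmented image carries full
#' provenance.
#'
#' @param values `h x w x L` array, values in `[0, 1]`.
#' @param method One of `"fd_a"`, `"fd_d"`, `"bs_fd"`, `"bs_knn"`,
#'   `"flow"`.
#' @param params Named list of the parameters used (`delta_t`, `upsilon`,
#'   `n_b`, `delta_tb`, `estimator`, ... as applicable).
#' @return A `motion_map` object.
#' @export
motion_map <- function(values, method, params = list()) {
  if (length(dim(values)) == 2L) {
    values <- array(values, dim = c(dim(values), 1L))
  }
  stopifnot(length(dim(values)) == 3L, dim(values)[3] %in% c(1L, 3L))
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("motion map values must lie in [0, 1].")
  }
  structure(
    list(values = values, method = method, params = params),
    class = "motion_map"
  )
}

#' @export
print.motion_map <- function(x, ...) {
  d <- dim(x$values)
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<motion_map> %s, %dx%dx%d, %s\n", x$method, d[1], d[2], d[3], p))
  invisible(x)
}

#' @rdname motion_map
#' @param m A `motion_map`.
#' @export
n_layers <- function(m) dim(m$values)[3]

# Shared neighbour fetch honouring the boundary policy.
neighbours_fd <- function(seq, t, delta_t, boundary) {
  list(
    prev = get_frame(seq, t - delta_t, boundary),
    cur = get_frame(seq, t, boundary),
    nxt = get_frame(seq, t + delta_t, boundary)
  )
}

#' Three-frame differencing
#'
#' `frame_difference_abs()` is the absolute three-frame difference: the
#' mean of the absolute differences between the frame of interest and its
#' two neighbours at distance `delta_t`, scaled by `upsilon` and truncated
#' to the normalised range,
#' \deqn{FD_a = clip(\upsilon \cdot \tfrac12 (|F_t - F_{t-\Delta t}| +
#'   |F_t - F_{t+\Delta t}|)).}
#' Static pixels map to 0; any colour change in either direction raises
#' the value.
#'
#' `frame_difference_dir()` is the directional variant, centred at 0.5:
#' \deqn{FD_d = clip(\tfrac12 + \tfrac{\upsilon}{4}[(F_t - F_{t-\Delta t})
#'   + (F_{t+\Delta t} - F_{t-\Delta t})]).}
#' Pixels above 0.5 are increasing in their colour value across the
#' window, below 0.5 decreasing. Clipping is applied after scaling for
#' both variants so augmented images stay valid colour data even at large
#' `upsilon`.
#'
#' @param seq A [frame_sequence()].
#' @param t Frame of interest (source index).
#' @param delta_t Frame distance to the neighbours (frames of the stored
#'   sequence), >= 1. Larger values accentuate movement at the cost of
#'   spatial precision.
#' @param upsilon Difference scaling constant, >= 0. Values above 1 boost
#'   faint motion before truncation.
#' @param boundary `"clamp"` reuses the nearest existing frame when a
#'   neighbour falls outside the sequence (so every labelled frame can be
#'   augmented); `"strict"` errors.
#'
#' @return A 3-layer [motion_map()].
#' @export
#' @examples
#' sc <- scene_spec(objects = list(object_spec(trajectory = c(2, 0))))
#' fs <- generate_sequence(sc)$sequence
#' m <- frame_difference_abs(fs, t = 3, delta_t = 1, upsilon = 5)
#' range(m$values)
frame_difference_abs <- function(seq, t, delta_t = 1, upsilon = 1,
                                 boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(is_count(delta_t), upsilon >= 0)
  fr <- neighbours_fd(seq, t, delta_t, boundary)
  vals <- clamp01(upsilon * 0.5 * (abs(fr$cur - fr$prev) + abs(fr$cur - fr$nxt)))
  motion_map(vals, "fd_a",
             list(delta_t = delta_t, upsilon = upsilon, t = t))
}

#' @rdname frame_difference_abs
#' @export
frame_difference_dir <- function(seq, t, delta_t = 1, upsilon = 1,
                                 boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(is_count(delta_t), upsilon >= 0)
  fr <- neighbours_fd(seq, t, delta_t, boundary)
  vals <- clamp01(0.5 + (upsilon / 4) * ((fr$cur - fr$prev) + (fr$nxt - fr$prev)))
  motion_map(vals, "fd_d",
             list(delta_t = delta_t, upsilon = upsilon, t = t))
}

#' Background estimation by frame averaging
#'
#' Approximates the static background at frame `t` by averaging out the
#' foreground across `n_b` historic frames spaced `delta_tb` apart:
#' \deqn{F_b = \tfrac{1}{n_b} \sum_{i=1}^{n_b} F_{t - i \Delta t_b}.}
#'
#' @inheritParams frame_difference_abs
#' @param n_b Number of background frames averaged.
#' @param delta_tb Spacing between background frames (frames).
#' @return An `h x w x 3` array (a plain frame, not a motion map).
#' @export
background_frame <- function(seq, t, n_b = 10, delta_tb = 1,
                             boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(is_count(n_b), is_count(delta_tb))
  if (boundary == "strict") {
    earliest <- t - n_b * delta_tb
    if (earliest < seq$frame_index_origin) {
      avail <- floor((t - seq$frame_index_origin) / delta_tb)
      abort(sprintf(
        "insufficient history at frame %d: %d background frame(s) requested, %d available.",
        t, n_b, max(avail, 0)
      ), class = "motionaug_missing_frame")
    }
  }
  acc <- array(0, dim = dim(seq$frames[[1]]))
  for (i in seq_len(n_b)) {
    acc <- acc + get_frame(seq, t - i * delta_tb, boundary)
  }
  acc / n_b
}

#' Background subtraction through frame differencing
#'
#' Measures foreground-ness on a continuous scale as the signed distance
#' of the frame of interest from the averaged background, centred at 0.5
#' and scaled:
#' \deqn{BS_{FD} = clip(\tfrac12 + \tfrac{\upsilon}{2}(F_t - F_b)).}
#' Leaves the decision of what counts as moving to the downstream
#' detector rather than thresholding to a binary mask.
#'
#' @inheritParams background_frame
#' @param upsilon Scaling constant, >= 0.
#' @return A 3-layer [motion_map()].
#' @export
background_subtract_fd <- function(seq, t, n_b = 10, delta_tb = 1,
                                   upsilon = 1,
                                   boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(upsilon >= 0)
  fb <- background_frame(seq, t, n_b = n_b, delta_tb = delta_tb,
                         boundary = boundary)
  cur <- get_frame(seq, t, boundary)
  vals <- clamp01(0.5 + (upsilon / 2) * (cur - fb))
  motion_map(vals, "bs_fd",
             list(n_b = n_b, delta_tb = delta_tb, upsilon = upsilon, t = t))
}

#' KNN background classifier (per-pixel)
#'
#' A simplified per-pixel K-nearest-neighbour background subtractor: each
#' pixel keeps a buffer of its own values over the previous `history`
#' frames, and is classed foreground when the majority of its `k` nearest
#' samples (Euclidean distance in RGB) lie farther than `dist_threshold`.
#' There is no spatial neighbourhood and no foreground resampling — the
#' buffer is purely temporal, which keeps the classifier deterministic
#' and testable. The binary mask is returned as a 1-layer motion map with
#' values in \{0, 1\}.
#'
#' @inheritParams frame_difference_abs
#' @param history Number of preceding frames in the per-pixel buffer.
#' @param k Neighbours consulted; the pixel is foreground when more than
#'   `k/2` of them exceed the distance threshold.
#' @param dist_threshold RGB Euclidean distance beyond which a historic
#'   sample no longer supports the background class.
#' @return A 1-layer binary [motion_map()].
#' @export
background_subtract_knn <- function(seq, t, history = 50, k = 3,
                                    dist_threshold = 0.08,
                                    boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(is_count(history), is_count(k), dist_threshold >= 0)
  if (boundary == "strict" && t - history < seq$frame_index_origin) {
    abort(sprintf(
      "insufficient history at frame %d: %d frame(s) requested before it.",
      t, history
    ), class = "motionaug_missing_frame")
  }
  cur <- get_frame(seq, t, boundary)
  h <- dim(cur)[1]
  w <- dim(cur)[2]
  npx <- h * w
  # npx x history matrix of RGB distances between the current pixel and
  # its own history buffer.
  d2 <- matrix(0, npx, history)
  for (i in seq_len(history)) {
    past <- get_frame(seq, t - i, boundary)
    diff <- cur - past
    d2[, i] <- sqrt(as.vector(diff[, , 1]^2 + diff[, , 2]^2 + diff[, , 3]^2))
  }
  kk <- min(k, history)
  need <- floor(kk / 2) + 1  # strict majority
  fg <- apply(d2, 1, function(d) {
    sum(sort(d, partial = kk)[seq_len(kk)] > dist_threshold) >= need
  })
  motion_map(matrix(as.numeric(fg), h, w), "bs_knn",
             list(history = history, k = k,
                  dist_threshold = dist_threshold, t = t))
}

#' Collapse a 3-layer motion map to a single layer
#'
#' Averages the three layers per pixel — the reduction used when a single
#' movement layer is needed for red-channel replacement or PCA
#' augmentation.
#'
#' @param m A 3-layer [motion_map()].
#' @return A 1-layer [motion_map()] with the same method/params.
#' @export
collapse_layers <- function(m) {
  stopifnot(inherits(m, "motion_map"))
  if (n_layers(m) != 3L) {
    abort("collapse_layers() requires a 3-layer motion map.")
  }
  d <- dim(m$values)
  vals <- matrix((m$values[, , 1] + m$values[, , 2] + m$values[, , 3]) / 3,
                 d[1], d[2])
  motion_map(vals, m$method, c(m$params, list(collapsed = TRUE)))
}

#' Persist a motion map as PNG plus a JSON sidecar
#'
#' Single-layer maps are written as greyscale PNG, 3-layer maps as RGB
#' PNG (8-bit, so values are quantised to the 1/255 grid); the sidecar
#' `<path>.json` records method and parameters at full precision.
#'
#' @param m A [motion_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_motion_map <- function(m, path) {
  stopifnot(inherits(m, "motion_map"))
  vals <- m$values
  if (dim(vals)[3] == 1L) {
    png::writePNG(vals[, , 1], path)
  } else {
    png::writePNG(vals, path)
  }
  jsonlite::write_json(
    list(method = m$method, params = m$params, layers = dim(vals)[3]),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_motion_map
#' @export
read_motion_map <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(dim(img)) == 2L && meta$layers == 1L) {
    vals <- array(img, dim = c(dim(img), 1L))
  } else {
    vals <- img[, , seq_len(meta$layers), drop = FALSE]
  }
  motion_map(vals, meta$method, as.list(meta$params))
}
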