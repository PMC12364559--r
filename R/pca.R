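#' Fit a PCA colour-compression model
#'
#' Compresses the three RGB colour layers to two so that one image layer
#' is freed for movement information. Pixels from a random sample of
#' `n_t` training frames (or all of them) are stacked into a single
#' `(h*w*n_t) x 3` matrix — each row a pixel, each column a colour — and
#' the top two principal components are extracted and whitened so the
#' fitted scores have mean 0 and variance 1 per component. Because
#' whitened scores are unbounded, an affine range map is then fitted so
#' that 99.5% of the sampled scores land in `[0, 1]`, making the output
#' storable as image data; the map is part of the model and recorded in
#' provenance.
#'
#' Component signs are oriented so each component's largest-magnitude
#' coefficient is positive (eigenvector sign is otherwise arbitrary).
#' If the pixel cloud only varies in one direction (e.g. pure grey
#' frames), the second component's whitening scale is set to 0 with a
#' warning; a fully constant pixel cloud is a degenerate-variance error.
#'
#' @param train_frames List of `h x w x 3` arrays — training-split frames
#'   only (using val/test frames here would leak information into the
#'   augmentation).
#' @param n_t Number of frames sampled (without replacement); `NULL` or
#'   values >= the number available use all frames.
#' @param seed Integer seed for the frame sample; the fit is
#'   deterministic given it.
#'
#' @return A `pca_color_model`: `mean` (3-vector), `components` (3 x 2,
#'   columns p1, p2), `whitening_scale` (2-vector of inverse score sds),
#'   `range_offset`/`range_scale` (per-component affine map),
#'   `n_images_sampled`, `frame_ids`, `seed`.
#' @export
#' @examples
#' frames <- generate_sequence(scene_spec(background = "textured",
#'   objects = list(object_spec(trajectory = c(1, 1)))))$sequence$frames
#' model <- fit_pca_color(frames, seed = 7)
#' model$components
fit_pca_color <- function(train_frames, n_t = 500, seed = 1L) {
  if (length(train_frames) == 0) {
    abort("at least one training frame is required.")
  }
  ids <- names(train_frames) %||% sprintf("frame%04d", seq_along(train_frames))
  take <- length(train_frames)
  if (!is.null(n_t)) take <- min(as.integer(n_t), take)
  sel <- with_preserved_seed(seed, {
    sort(sample.int(length(train_frames), take))
  })
  px <- do.call(rbind, lapply(train_frames[sel], function(f) {
    matrix(f, ncol = 3)
  }))
  mu <- colMeans(px)
  centred <- sweep(px, 2, mu)
  cv <- crossprod(centred) / (nrow(centred) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  tol <- max(eig$values[1], 0) * 1e-10
  if (eig$values[1] <= .Machine$double.eps) {
    abort(
      "degenerate variance: pixel values are constant, PCA colour compression is undefined.",
      class = "motionaug_degenerate_variance"
    )
  }
  comps <- eig$vectors[, 1:2, drop = FALSE]
  # Reproducible sign: largest-|coefficient| entry positive.
  for (j in 1:2) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  scores <- centred %*% comps
  sds <- apply(scores, 2, stats::sd)
  wscale <- ifelse(eig$values[1:2] > tol & sds > 0, 1 / sds, 0)
  if (any(wscale == 0)) {
    warn("pixel cloud varies in fewer than 2 directions; the degenerate component's whitening scale is 0.")
  }
  white <- sweep(scores, 2, wscale, `*`)
  # Affine map putting the central 99.5% of fitted whitened scores in
  # [0, 1]: x -> (x - q_lo) / (q_hi - q_lo).
  q <- apply(white, 2, quantile, probs = c(0.0025, 0.9975), names = FALSE)
  span <- q[2, ] - q[1, ]
  span[span <= 0] <- 1
  model <- structure(
    list(
      mean = mu,
      components = comps,
      whitening_scale = wscale,
      range_offset = q[1, ],
      range_scale = 1 / span,
      n_images_sampled = take,
      frame_ids = ids[sel],
      seed = as.integer(seed)
    ),
    class = "pca_color_model"
  )
  model
}

#' @export
print.pca_color_model <- function(x, ...) {
  cat(sprintf(
    "<pca_color_model> fitted on %d frame(s), seed %d\n p1 = (%s)\n p2 = (%s)\n",
    x$n_images_sampled, x$seed,
    paste(sprintf("%.4f", x$components[, 1]), collapse = ", "),
    paste(sprintf("%.4f", x$components[, 2]), collapse = ", ")
  ))
  invisible(x)
}

# Whitened (pre-range-map) scores of an n x 3 pixel matrix.
pca_whitened_scores <- function(model, px) {
  sweep(sweep(px, 2, model$mean) %*% model$components, 2,
        model$whitening_scale, `*`)
}

#' Apply a PCA colour model to a frame
#'
#' Per pixel: subtract the fitted channel means, project on (p1, p2),
#' whiten, apply the model's affine range map and clip to `[0, 1]`.
#'
#' @param model A [fit_pca_color()] model.
#' @param frame `h x w x 3` array in `[0, 1]`.
#' @return An `h x w x 2` array in `[0, 1]` (component-1 and component-2
#'   layers).
#' @export
apply_pca_color <- function(model, frame) {
  stopifnot(inherits(model, "pca_color_model"))
  d <- dim(frame)
  white <- pca_whitened_scores(model, matrix(frame, ncol = 3))
  mapped <- sweep(sweep(white, 2, model$range_offset), 2,
                  model$range_scale, `*`)
  clamp01(array(mapped, dim = c(d[1], d[2], 2L)))
}

#' Persist / restore a PCA colour model as JSON
#'
#' Numbers are serialised as 17-significant-digit decimal strings so a
#' reloaded model reproduces transforms bit-exactly.
#'
#' @param model A [fit_pca_color()] model.
#' @param path JSON file path.
#' @return `path` / the restored model.
#' @export
write_pca_model <- function(model, path) {
  full <- function(x) sprintf("%.17g", x)
  jsonlite::write_json(
    list(
      mean = full(model$mean),
      components = full(as.vector(model$components)),
      whitening_scale = full(model$whitening_scale),
      range_offset = full(model$range_offset),
      range_scale = full(model$range_scale),
      n_images_sampled = model$n_images_sampled,
      frame_ids = model$frame_ids,
      seed = model$seed
    ),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      mean = as.numeric(x$mean),
      components = matrix(as.numeric(unlist(x$components)), ncol = 2),
      whitening_scale = as.numeric(x$whitening_scale),
      range_offset = as.numeric(x$range_offset),
      range_scale = as.numeric(x$range_scale),
      n_images_sampled = as.integer(x$n_images_sampled),
      frame_ids = as.character(x$frame_ids),
      seed = as.integer(x$seed)
    ),
    class = "pca_color_model"
  )
}
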