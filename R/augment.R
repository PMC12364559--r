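#' Combine colour and movement layers into an augmented image
#'
#' Three strategies fold movement information into an ordinary 3-layer
#' RGB image, so any off-the-shelf object detector can consume it:
#'
#' * `augment_replace_all()` — the whole image becomes the 3-layer motion
#'   map (all colour information replaced by movement).
#' * `augment_replace_red()` — the red layer (often nearly empty in
#'   underwater footage, where water absorbs red light first) is replaced
#'   by a single movement layer; green and blue pass through untouched.
#' * `augment_pca()` — green and blue become the two PCA-compressed
#'   colour layers of the original frame and red becomes the movement
#'   layer, so (compressed) colour is retained alongside movement.
#'
#' Augmentation never moves pixels, so bounding-box labels are unchanged
#' by construction.
#'
#' @param frame `h x w x 3` array in `[0, 1]`.
#' @param motion3 A 3-layer [motion_map()].
#' @param motion1 A 1-layer [motion_map()] (use [collapse_layers()] for
#'   differencing maps or [flow_to_layers()] `magnitude1` for flow; a KNN
#'   mask is already single-layer).
#' @param model A fitted [fit_pca_color()] model (train-split frames
#'   only).
#'
#' @return An `augmented_image`: `values` (`h x w x 3` in `[0, 1]`),
#'   `mode` (`"all"`, `"red"` or `"pca"`) and `provenance` (motion method
#'   and parameters, plus the PCA seed for `"pca"`).
#' @export
#' @examples
#' sc <- scene_spec(objects = list(object_spec(trajectory = c(2, 0))))
#' fs <- generate_sequence(sc)$sequence
#' m <- frame_difference_abs(fs, t = 3, delta_t = 1, upsilon = 5)
#' a <- augment_replace_red(get_frame(fs, 3), collapse_layers(m))
#' a$mode
augment_replace_all <- function(frame, motion3) {
  check_motion_shape(frame, motion3, layers = 3L)
  augmented_image(motion3$values, "all", motion3)
}

#' @rdname augment_replace_all
#' @export
augment_replace_red <- function(frame, motion1) {
  check_motion_shape(frame, motion1, layers = 1L)
  vals <- frame
  vals[, , 1] <- motion1$values[, , 1]
  augmented_image(vals, "red", motion1)
}

#' @rdname augment_replace_all
#' @export
augment_pca <- function(frame, motion1, model) {
  check_motion_shape(frame, motion1, layers = 1L)
  if (!inherits(model, "pca_color_model")) {
    abort("`model` must be a fitted pca_color_model.")
  }
  comp <- apply_pca_color(model, frame)
  vals <- array(0, dim = dim(frame))
  vals[, , 1] <- motion1$values[, , 1]
  vals[, , 2] <- comp[, , 1]
  vals[, , 3] <- comp[, , 2]
  augmented_image(vals, "pca", motion1, pca_seed = model$seed)
}

check_motion_shape <- function(frame, m, layers) {
  if (!inherits(m, "motion_map")) {
    abort("`motion` must be a motion_map.")
  }
  if (n_layers(m) != layers) {
    abort(sprintf("a %d-layer motion map is required.", layers))
  }
  if (!all(dim(frame)[1:2] == dim(m$values)[1:2])) {
    abort("frame and motion map shapes do not match.")
  }
  invisible(TRUE)
}

augmented_image <- function(values, mode, motion, pca_seed = NULL) {
  structure(
    list(
      values = values,
      mode = mode,
      provenance = list(
        method = motion$method,
        params = motion$params,
        pca_seed = pca_seed
      )
    ),
    class = "augmented_image"
  )
}

#' @export
print.augmented_image <- function(x, ...) {
  cat(sprintf(
    "<augmented_image> mode %s, motion %s\n", x$mode, x$provenance$method
  ))
  invisible(x)
}

# Compute the motion map a config asks for at frame t of seq; returns a
# 3-layer map for mode 'all' and a 1-layer map otherwise.
config_motion <- function(seq, t, config, want_layers) {
  method <- config$method
  boundary <- config$boundary %||% "clamp"
  if (method == "fd") {
    f <- if ((config$approach %||% "FD_a") == "FD_d") {
      frame_difference_dir
    } else {
      frame_difference_abs
    }
    m <- f(seq, t, delta_t = config$delta_t %||% 1,
           upsilon = config$upsilon %||% 1, boundary = boundary)
    if (want_layers == 1L) m <- collapse_layers(m)
    return(m)
  }
  if (method == "bs_fd") {
    m <- background_subtract_fd(
      seq, t, n_b = config$n_b %||% 10, delta_tb = config$delta_tb %||% 1,
      upsilon = config$upsilon %||% 1, boundary = boundary
    )
    if (want_layers == 1L) m <- collapse_layers(m)
    return(m)
  }
  if (method == "bs_knn") {
    m <- background_subtract_knn(
      seq, t, history = config$history %||% 50, k = config$k %||% 3,
      dist_threshold = config$dist_threshold %||% 0.08, boundary = boundary
    )
    if (want_layers == 3L) {
      m <- motion_map(array(rep(m$values[, , 1], 3),
                            dim = c(dim(m$values)[1:2], 3L)),
                      m$method, m$params)
    }
    return(m)
  }
  if (method == "flow") {
    fl <- flow_field(seq, t, delta_t = config$delta_t %||% 1,
                     estimator = config$estimator %||% "block_match",
                     boundary = boundary)
    mode <- if (want_layers == 1L) "magnitude1" else "hsv3"
    return(flow_to_layers(fl, mode = mode))
  }
  abort(sprintf("unknown motion method '%s'.", method))
}

#' Augment a whole labelled dataset
#'
#' Runs the full augmentation workflow over a dataset manifest: for every
#' labelled image, the surrounding sequence is consulted, the configured
#' motion measure computed at the labelled frame, the configured
#' augmentation applied, and the result written in YOLO dataset layout
#' (`images/<split>/<stem>.png`, `labels/<split>/<stem>.txt`,
#' `dataset.yaml` with the class table). Label files are copied byte for
#' byte — augmentation never moves boxes. `method = "raw"` copies images
#' byte-identically (the unaugmented baseline).
#'
#' For `mode = "pca"` the colour model is fitted on train-split frames
#' only and reused frozen for val/test (fitting on evaluation frames
#' would leak); the run log records the fitted frame ids so the guard is
#' auditable.
#'
#' A JSON-lines run log (`runlog.jsonl` in `out_dir`) records the config,
#' seed, per-image boundary-policy hits and any per-image errors; with
#' `strict = FALSE` (default) unresolvable frames are collected and
#' reported while the run continues.
#'
#' @param manifest Manifest list from [read_manifest()] (or
#'   [write_scene_dataset()]).
#' @param config Augmentation config — a one-row tibble from
#'   [augmentation_config()] / [expand_augmentation_grid()], or an
#'   equivalent named list.
#' @param out_dir Output dataset root.
#' @param strict Abort on the first unresolvable frame instead of
#'   logging it.
#'
#' @return Invisibly, a list with `written` (tibble of image/split/path),
#'   `errors` (character), `run_log` (path), `pca_model` (path or NULL).
#' @export
augment_dataset <- function(manifest, config, out_dir, strict = FALSE) {
  if (inherits(config, "data.frame")) {
    stopifnot(nrow(config) == 1L)
    config <- as.list(config)
    config <- config[!vapply(config, function(x) is.na(x)[1], logical(1))]
  }
  method <- config$method
  mode <- config$mode %||% "all"
  entries <- manifest$entries
  root <- manifest$root
  for (s in unique(entries$split)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  log_path <- file.path(out_dir, "runlog.jsonl")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), log_con)
  }
  log_line(list(event = "start", config = config))

  # Sequences are loaded once each; fixture datasets are small.
  seq_cache <- new.env(parent = emptyenv())
  load_seq <- function(name) {
    if (!exists(name, envir = seq_cache)) {
      assign(name, read_sequence(file.path(root, "sequences", name)),
             envir = seq_cache)
    }
    get(name, envir = seq_cache)
  }

  pca_model <- NULL
  pca_path <- NULL
  if (method != "raw" && mode == "pca") {
    train <- dplyr::filter(entries, .data$split == "train")
    if (nrow(train) == 0) {
      abort("mode 'pca' requires train-split entries to fit the colour model.")
    }
    frames <- purrr::map2(train$sequence, train$frame, function(sq, fr) {
      get_frame(load_seq(sq), fr)
    })
    names(frames) <- train$image
    pca_model <- fit_pca_color(frames, n_t = config$n_t %||% 500,
                               seed = config$seed %||% 1L)
    pca_path <- file.path(out_dir, "pca_model.json")
    write_pca_model(pca_model, pca_path)
    log_line(list(event = "pca_fit", split = "train",
                  frame_ids = pca_model$frame_ids, seed = pca_model$seed))
  }

  errors <- character()
  written <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    img_out <- file.path(out_dir, "images", e$split, paste0(e$image, ".png"))
    lbl_in <- file.path(root, "labels", paste0(e$image, ".txt"))
    lbl_out <- file.path(out_dir, "labels", e$split, paste0(e$image, ".txt"))
    res <- tryCatch({
      sq <- load_seq(e$sequence)
      last <- sq$frame_index_origin + n_frames(sq) - 1L
      if (e$frame < sq$frame_index_origin || e$frame > last) {
        abort(sprintf("frame %d of '%s' is not loaded.", e$frame, e$sequence),
              class = "motionaug_missing_frame")
      }
      if (method == "raw") {
        src <- file.path(root, "sequences", e$sequence,
                         sprintf("frame_%06d.png", e$frame))
        file.copy(src, img_out, overwrite = TRUE)
      } else {
        frame <- get_frame(sq, e$frame)
        aug <- switch(mode,
          all = augment_replace_all(
            frame, config_motion(sq, e$frame, config, want_layers = 3L)),
          red = augment_replace_red(
            frame, config_motion(sq, e$frame, config, want_layers = 1L)),
          pca = augment_pca(
            frame, config_motion(sq, e$frame, config, want_layers = 1L),
            pca_model),
          abort(sprintf("unknown augmentation mode '%s'.", mode))
        )
        write_image(aug$values, img_out)
      }
      file.copy(lbl_in, lbl_out, overwrite = TRUE)
      # Boundary-policy hit: a neighbour or history frame was clamped.
      dt <- config$delta_t %||% 1
      hit <- method %in% c("fd", "flow") &&
        (e$frame - dt < sq$frame_index_origin || e$frame + dt > last)
      if (method == "bs_fd") {
        hit <- e$frame - (config$n_b %||% 10) * (config$delta_tb %||% 1) <
          sq$frame_index_origin
      }
      log_line(list(event = "image", image = e$image, split = e$split,
                    boundary_clamped = hit))
      TRUE
    }, error = function(err) {
      if (strict) stop(err)
      msg <- conditionMessage(err)
      log_line(list(event = "error", image = e$image, message = msg))
      errors <<- c(errors, sprintf("%s: %s", e$image, msg))
      FALSE
    })
    written[[i]] <- tibble::tibble(
      image = e$image, split = e$split, path = img_out, ok = res
    )
  }
  yaml::write_yaml(
    list(path = out_dir, names = as.list(manifest$classes),
         nc = length(manifest$classes)),
    file.path(out_dir, "dataset.yaml")
  )
  log_line(list(event = "done", n_errors = length(errors)))
  invisible(list(
    written = dplyr::bind_rows(written),
    errors = errors,
    run_log = log_path,
    pca_model = pca_path
  ))
}
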