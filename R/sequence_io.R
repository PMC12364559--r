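#' Read a frame sequence from an image-burst folder
#'
#' Loads a window of frames from a folder of lexically ordered PNG or JPEG
#' images into a [frame_sequence()]. 8-bit inputs map to `[0, 1]` by
#' `value / 255` (the PNG reader already applies this, so a stored byte of
#' 255 becomes exactly 1.0). Greyscale images are expanded to three equal
#' channels; an alpha channel, if present, is dropped.
#'
#' Video containers (MP4/AVI) are not decodable by any codec available to
#' this package; passing one raises a capability error. Burst folders of
#' PNG frames are the canonical, bit-stable path: decode videos to numbered
#' frames first (e.g. with ffmpeg) and point `read_sequence()` at the
#' folder.
#'
#' @param path Folder containing numbered image files.
#' @param window Optional `c(first, last)` 1-based frame indices within the
#'   folder's lexical order; `NULL` loads everything.
#' @param source_id Identifier stored on the sequence; defaults to the
#'   folder name.
#' @param frame_interval Optional seconds between frames.
#'
#' @return A [frame_sequence()] with `frame_index_origin = window[1]`.
#' @export
read_sequence <- function(path, window = NULL, source_id = NULL,
                          frame_interval = NULL) {
  if (file.exists(path) && !dir.exists(path)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", tolower(path))) {
      abort(
        paste0(
          "video container '", basename(path), "' cannot be decoded: no ",
          "video codec is available to motionaug. Extract frames to a PNG ",
          "folder first and pass the folder."
        ),
        class = "motionaug_capability_error"
      )
    }
    abort(sprintf("'%s' is not a readable sequence folder.", path))
  }
  if (!dir.exists(path)) {
    abort(sprintf("sequence folder '%s' does not exist.", path))
  }
  files <- list.files(path, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  files <- sort(files)
  if (length(files) == 0) {
    abort(sprintf("no PNG/JPEG frames found in '%s'.", path))
  }
  if (is.null(window)) {
    window <- c(1L, length(files))
  }
  first <- as.integer(window[1])
  last <- as.integer(window[2])
  if (first < 1L || last > length(files) || first > last) {
    abort(sprintf(
      "window [%d, %d] is outside the available frames [1, %d] of '%s'.",
      first, last, length(files), path
    ), class = "motionaug_missing_frame")
  }
  frames <- lapply(files[first:last], function(f) {
    read_image(file.path(path, f))
  })
  frame_sequence(
    frames,
    frame_index_origin = first,
    source_id = source_id %||% basename(path),
    frame_interval = frame_interval
  )
}

#' Write a frame sequence as a numbered PNG folder
#'
#' Frames are written as `frame_000001.png`, `frame_000002.png`, ...
#' (numbered by source index). PNG storage is 8-bit, so values are
#' quantised to the 1/255 grid; sequences whose values already lie on that
#' grid round-trip bit-identically.
#'
#' @param seq A [frame_sequence()].
#' @param path Output folder (created if needed).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx <- seq$frame_index_origin + seq_along(seq$frames) - 1L
  for (i in seq_along(seq$frames)) {
    png::writePNG(
      seq$frames[[i]],
      file.path(path, sprintf("frame_%06d.png", idx[i]))
    )
  }
  invisible(path)
}

# Read one image file to an h x w x 3 array in [0, 1].
read_image <- function(file) {
  if (grepl("\\.png$", tolower(file))) {
    img <- png::readPNG(file)
  } else {
    abort(sprintf("unsupported image format: '%s' (PNG expected).", file))
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 2L) {
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3L))
  }
  img
}

write_image <- function(frame, file) {
  png::writePNG(clamp01(frame), file)
  invisible(file)
}

#' Resize an image together with its annotations
#'
#' Pixel data are resampled bilinearly (centre-aligned, edge-clamped; a 2x
#' downsample averages 2x2 blocks exactly). Normalised YOLO boxes are
#' scale-free, so the annotations are returned unchanged — the function
#' exists so that pipelines carry boxes and pixels through resizing as one
#' unit.
#'
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param target `c(height, width)` in pixels.
#'
#' @return A list with elements `image` and `annotations`.
#' @export
resize_with_annotations <- function(image, annotations, target) {
  stopifnot(length(target) == 2L, all(target >= 1))
  out <- bilinear_resample_frame(image, as.integer(target[1]),
                                 as.integer(target[2]))
  list(image = clamp01(out), annotations = annotations)
}
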