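#' YOLO-format annotations and detections
#'
#' Annotations are plain tibbles with columns `class_id` (integer >= 0),
#' `cx`, `cy`, `bw`, `bh` (box centre and size normalised to `[0, 1]`) and
#' `image_ref` (identifier of the labelled image). Detections carry an
#' additional `score` column in `[0, 1]`.
#'
#' On disk the dialect is the YOLO text format: one line per box,
#' `class cx cy w h`, whitespace-separated normalised floats, one file per
#' image. A trailing sixth token is read as the confidence score, so the
#' same parser serves ground truth and predictions.
#'
#' The internal corner convention is 0-based, half-open, x right / y down:
#' a box covers pixels `[x1, x2) x [y1, y2)` so that `width = x2 - x1`.
#'
#' @param path Annotation text file.
#' @param image_ref Identifier attached to every parsed box; defaults to
#'   the file stem.
#'
#' @return `read_annotations()`: a tibble with one row per box (zero rows
#'   for an empty file), with a `score` column only when any line carried
#'   a sixth token.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("0 0.5 0.5 0.2 0.1", f)
#' read_annotations(f)
read_annotations <- function(path, image_ref = NULL) {
  image_ref <- image_ref %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_annotations())
  }
  toks <- strsplit(lines, "\\s+")
  nt <- lengths(toks)
  if (any(!nt %in% c(5L, 6L))) {
    abort(sprintf(
      "malformed annotation lines (expected 5 or 6 tokens) at line(s): %s",
      paste(which(!nt %in% c(5L, 6L)), collapse = ", ")
    ))
  }
  m <- t(vapply(toks, function(x) as.numeric(x[1:5]), numeric(5)))
  ann <- tibble::tibble(
    image_ref = image_ref,
    class_id = as.integer(m[, 1]),
    cx = m[, 2], cy = m[, 3], bw = m[, 4], bh = m[, 5]
  )
  if (any(nt == 6L)) {
    ann$score <- vapply(
      toks,
      function(x) if (length(x) == 6L) as.numeric(x[6]) else NA_real_,
      numeric(1)
    )
  }
  validate_annotations(ann, path = path)
  ann
}

empty_annotations <- function() {
  tibble::tibble(
    image_ref = character(), class_id = integer(),
    cx = double(), cy = double(), bw = double(), bh = double()
  )
}

# Boxes must convert to corners inside [0,1]^2 with positive size; scores,
# if present, must be in [0,1].  Reports offending line numbers.
validate_annotations <- function(ann, path = "<annotations>") {
  if (nrow(ann) == 0) {
    return(invisible(ann))
  }
  bad <- ann$class_id < 0 |
    ann$bw <= 0 | ann$bh <= 0 |
    ann$cx - ann$bw / 2 < -1e-9 | ann$cx + ann$bw / 2 > 1 + 1e-9 |
    ann$cy - ann$bh / 2 < -1e-9 | ann$cy + ann$bh / 2 > 1 + 1e-9
  if ("score" %in% names(ann)) {
    bad <- bad | (!is.na(ann$score) & (ann$score < 0 | ann$score > 1))
  }
  if (any(bad)) {
    abort(sprintf(
      "invalid box coordinates in %s at line(s): %s",
      path, paste(which(bad), collapse = ", ")
    ), class = "motionaug_annotation_error")
  }
  invisible(ann)
}

#' @rdname read_annotations
#' @param annotations Annotation (or detection) tibble.
#' @param digits Decimal places written (>= 6 so a write/read round trip
#'   preserves boxes to 1e-6).
#' @export
write_annotations <- function(annotations, path, digits = 8) {
  stopifnot(digits >= 6)
  validate_annotations(annotations)
  fmt <- paste0("%.", digits, "f")
  if (nrow(annotations) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf(
    paste("%d", fmt, fmt, fmt, fmt),
    annotations$class_id, annotations$cx, annotations$cy,
    annotations$bw, annotations$bh
  )
  if ("score" %in% names(annotations) && !all(is.na(annotations$score))) {
    lines <- paste(lines, sprintf(fmt, annotations$score))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalised centre boxes to corner form
#'
#' Corners are half-open (`width = x2 - x1`) in normalised units, or in
#' pixels when `height`/`width` are supplied.
#'
#' @param annotations Annotation tibble.
#' @param height,width Optional pixel dimensions for pixel-space corners.
#' @return The tibble with columns `x1`, `y1`, `x2`, `y2` appended.
#' @export
boxes_to_corners <- function(annotations, height = NULL, width = NULL) {
  sx <- width %||% 1
  sy <- height %||% 1
  dplyr::mutate(
    annotations,
    x1 = (.data$cx - .data$bw / 2) * sx,
    y1 = (.data$cy - .data$bh / 2) * sy,
    x2 = (.data$cx + .data$bw / 2) * sx,
    y2 = (.data$cy + .data$bh / 2) * sy
  )
}

#' Dataset manifests
#'
#' A manifest links every labelled image to its position within its
#' surrounding sequence — the piece of bookkeeping that makes movement
#' information recoverable for a labelled still. It is stored as YAML with
#' a class-name table and one entry per labelled image:
#' `image` (id, also the label-file stem), `sequence` (burst-folder name
#' under the dataset root), `frame` (1-based index within the sequence)
#' and `split` (`train`, `val` or `test`).
#'
#' @param path Manifest YAML file.
#' @return A list with elements `root` (dataset root directory, taken as
#'   the manifest's folder unless the YAML overrides it), `classes`
#'   (character vector) and `entries` (tibble).
#' @export
read_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- dplyr::bind_rows(lapply(doc$entries, tibble::as_tibble))
  required <- c("image", "sequence", "frame", "split")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    abort(sprintf(
      "manifest '%s' entries lack field(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(entries$image)) {
    abort(sprintf("manifest '%s' has duplicate image ids.", path))
  }
  if (!all(entries$split %in% c("train", "val", "test"))) {
    abort("manifest splits must be one of train/val/test.")
  }
  list(
    root = doc$root %||% dirname(path),
    classes = as.character(doc$classes),
    entries = dplyr::mutate(entries, frame = as.integer(.data$frame))
  )
}

#' @rdname read_manifest
#' @param manifest Manifest list as returned by `read_manifest()`.
#' @export
write_manifest <- function(manifest, path) {
  doc <- list(
    classes = as.list(manifest$classes),
    entries = purrr::pmap(
      manifest$entries[, c("image", "sequence", "frame", "split")],
      function(image, sequence, frame, split) {
        list(image = image, sequence = sequence,
             frame = as.integer(frame), split = split)
      }
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
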