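#' Frame sequences
#'
#' A `frame_sequence` is the container every motion measure reads from: an
#' ordered list of `h x w x 3` numeric arrays (RGB, values in `[0, 1]`),
#' together with the index of the first loaded frame within its source, a
#' source identifier, and optionally the real-time interval between frames.
#'
#' Frames are indexed by their *source* frame number: `get_frame(seq, t)`
#' returns the frame whose index within the original video or burst folder
#' is `t`, regardless of which window was loaded.
#'
#' @param frames List of `h x w x 3` arrays with values in `[0, 1]`.
#' @param frame_index_origin Integer source index of `frames[[1]]` (1-based).
#' @param source_id Identifier of the originating video/burst folder.
#' @param frame_interval Optional seconds between consecutive frames.
#'
#' @return A `frame_sequence` object.
#' @export
#' @examples
#' f <- array(0.5, dim = c(4, 4, 3))
#' fs <- frame_sequence(list(f, f, f))
#' n_frames(fs)
frame_sequence <- function(frames, frame_index_origin = 1L,
                           source_id = "sequence", frame_interval = NULL) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of h x w x 3 arrays.")
  }
  dims <- lapply(frames, dim)
  ok <- vapply(dims, function(d) length(d) == 3L && d[3] == 3L, logical(1))
  if (!all(ok)) {
    abort("every frame must be an h x w x 3 array.")
  }
  hw <- dims[[1]][1:2]
  same <- vapply(dims, function(d) all(d[1:2] == hw), logical(1))
  if (!all(same)) {
    abort("all frames must share the same (height, width).")
  }
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1) {
    abort("frame values must lie within [0, 1].")
  }
  if (!is_count(frame_index_origin, min = 0L)) {
    abort("`frame_index_origin` must be a non-negative integer.")
  }
  structure(
    list(
      frames = frames,
      frame_index_origin = as.integer(frame_index_origin),
      source_id = source_id,
      frame_interval = frame_interval
    ),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<frame_sequence> %d frame(s) of %dx%d px, source '%s', origin %d\n",
    length(x$frames), d[1], d[2], x$source_id, x$frame_index_origin
  ))
  invisible(x)
}

#' @rdname frame_sequence
#' @param seq A `frame_sequence`.
#' @export
n_frames <- function(seq) length(seq$frames)

#' @rdname frame_sequence
#' @export
frame_height <- function(seq) dim(seq$frames[[1]])[1]

#' @rdname frame_sequence
#' @export
frame_width <- function(seq) dim(seq$frames[[1]])[2]

#' Fetch a frame by source index
#'
#' @param seq A [frame_sequence()].
#' @param t Source frame index.
#' @param boundary `"strict"` errors when `t` falls outside the loaded
#'   window; `"clamp"` (the default policy used throughout the motion
#'   measures) reuses the nearest loaded frame so that the first and last
#'   frames of a sequence can still be differenced and augmented.
#'
#' @return An `h x w x 3` array.
#' @export
get_frame <- function(seq, t, boundary = c("clamp", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(seq, "frame_sequence"))
  pos <- t - seq$frame_index_origin + 1L
  n <- n_frames(seq)
  if (pos < 1L || pos > n) {
    if (boundary == "strict") {
      abort(sprintf(
        "frame %d is outside the loaded window [%d, %d] of source '%s'.",
        t, seq$frame_index_origin, seq$frame_index_origin + n - 1L,
        seq$source_id
      ), class = "motionaug_missing_frame")
    }
    pos <- min(max(pos, 1L), n)
  }
  seq$frames[[pos]]
}
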