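#' Intersection over union of two boxes
#'
#' Boxes are in corner form `c(x1, y1, x2, y2)`, half-open (`width =
#' x2 - x1`), in any common unit (normalised or pixels — IOU is
#' scale-free).
#'
#' @param a,b Boxes `c(x1, y1, x2, y2)`.
#' @return Overlap area divided by union area, in `[0, 1]`; 0 when
#'   disjoint.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
iou <- function(a, b) {
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) {
    abort("boxes must have positive area.")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) {
    return(0)
  }
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

# Corner-form matrices for a detection/annotation tibble.
corners_matrix <- function(tbl) {
  cbind(
    tbl$cx - tbl$bw / 2, tbl$cy - tbl$bh / 2,
    tbl$cx + tbl$bw / 2, tbl$cy + tbl$bh / 2
  )
}

# Greedy matching in descending score order; returns logical TP flags per
# detection (in the order of `dets`), for one class.  A detection matches
# the highest-IOU unmatched ground-truth box on its image when that IOU
# reaches the threshold; IOU ties break by ground-truth input order,
# score ties by detection input order (sort is stable).
match_detections <- function(dets, gts, iou_thresh) {
  ord <- order(-dets$score)
  db <- corners_matrix(dets)
  gb <- corners_matrix(gts)
  gt_used <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(dets))
  for (i in ord) {
    cand <- which(gts$image_ref == dets$image_ref[i] & !gt_used)
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j) iou(db[i, ], gb[j, ]), numeric(1))
    best <- which.max(ious)  # first max -> GT input order breaks ties
    if (ious[best] >= iou_thresh) {
      tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  list(tp = tp, order = ord)
}

#' Average precision for one class
#'
#' Greedy score-ordered matching against ground truth at a fixed IOU
#' threshold, then the area under the all-point interpolated
#' precision-recall curve (the PASCAL metric): at each achieved recall
#' level the precision is replaced by the maximum precision at any equal
#' or higher recall, and the curve is integrated across recall
#' increments.
#'
#' @param dets Detection tibble (columns of [read_annotations()] plus
#'   `score`).
#' @param gts Ground-truth annotation tibble.
#' @param class_id Class evaluated.
#' @param iou_thresh IOU threshold for a true positive.
#' @return AP in `[0, 1]`; 0 when the class has ground truth but no
#'   detections; `NA` when the class has no ground truth (undefined,
#'   excluded from mAP).
#' @export
average_precision <- function(dets, gts, class_id, iou_thresh = 0.5) {
  g <- dplyr::filter(gts, .data$class_id == !!class_id)
  d <- dplyr::filter(dets, .data$class_id == !!class_id)
  if (nrow(g) == 0) {
    return(NA_real_)
  }
  if (nrow(d) == 0) {
    return(0)
  }
  m <- match_detections(d, g, iou_thresh)
  tp <- m$tp[m$order]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / nrow(g)
  precision <- cum_tp / (cum_tp + cum_fp)
  ap_all_point(recall, precision)
}

# All-point interpolated area under the PR curve.
ap_all_point <- function(recall, precision) {
  r <- c(0, recall, 1)
  p <- c(0, precision, 0)
  # Monotone envelope from the right: p[i] = max(p[i], p[i+1], ...).
  for (i in rev(seq_len(length(p) - 1))) {
    p[i] <- max(p[i], p[i + 1])
  }
  idx <- which(r[-1] != r[-length(r)]) + 1
  sum((r[idx] - r[idx - 1]) * p[idx])
}

#' mAP at the standard thresholds
#'
#' Evaluates detections against ground truth at IOU 0.50, 0.75 and the
#' ten thresholds 0.50, 0.55, ..., 0.95. `mAP@tau` is the unweighted mean
#' of per-class AP over classes with at least one ground-truth box;
#' `mAP@50:95` is the mean of the ten per-threshold mAPs. Classes with
#' detections but no ground truth contribute nothing (logged in the
#' result); classes with ground truth but no detections contribute AP 0.
#'
#' @inheritParams average_precision
#' @param thresholds IOU thresholds evaluated.
#' @return A `map_eval` object; see [tidy.map_eval()] for the per-class
#'   table and [glance.map_eval()] for the headline metrics.
#' @export
#' @examples
#' gt <- tibble::tibble(image_ref = "a", class_id = 0L,
#'                      cx = 0.5, cy = 0.5, bw = 0.2, bh = 0.2)
#' det <- dplyr::mutate(gt, score = 0.9)
#' glance(map_suite(det, gt))
map_suite <- function(dets, gts,
                      thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(gts) == 0) {
    abort("ground truth is empty; mAP is undefined.")
  }
  if (!"score" %in% names(dets)) {
    dets$score <- 1
  }
  gt_classes <- sort(unique(gts$class_id))
  ghost <- setdiff(unique(dets$class_id), gt_classes)
  thresholds <- sort(unique(c(thresholds, 0.5, 0.75)))
  per_class <- tidyr::expand_grid(
    class_id = gt_classes, iou_thresh = thresholds
  )
  per_class$ap <- purrr::map2_dbl(
    per_class$class_id, per_class$iou_thresh,
    function(cl, th) average_precision(dets, gts, cl, th)
  )
  counts <- dplyr::count(gts, .data$class_id, name = "n_gt")
  per_class <- dplyr::left_join(per_class, counts, by = "class_id")
  map_tbl <- dplyr::summarise(
    dplyr::group_by(per_class, .data$iou_thresh),
    map = mean(.data$ap), .groups = "drop"
  )
  coco <- seq(0.5, 0.95, by = 0.05)
  structure(
    list(
      per_class = per_class,
      per_threshold = map_tbl,
      map50 = map_tbl$map[map_tbl$iou_thresh == 0.5],
      map75 = map_tbl$map[map_tbl$iou_thresh == 0.75],
      map50_95 = mean(map_tbl$map[map_tbl$iou_thresh %in% coco]),
      unmatched_det_classes = ghost
    ),
    class = "map_eval"
  )
}

#' @export
print.map_eval <- function(x, ...) {
  cat(sprintf(
    "<map_eval> mAP@50 = %.4f, mAP@75 = %.4f, mAP@50:95 = %.4f (%d class(es))\n",
    x$map50, x$map75, x$map50_95, length(unique(x$per_class$class_id))
  ))
  if (length(x$unmatched_det_classes) > 0) {
    cat(" detections with no ground truth for class(es):",
        paste(x$unmatched_det_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-class AP table
#'
#' @param x A [map_suite()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble of `class_id`, `iou_thresh`, `ap`, `n_gt`;
#'   `glance()`: one-row tibble of `map50`, `map75`, `map50_95`.
#' @export
tidy.map_eval <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.map_eval
#' @export
glance.map_eval <- function(x, ...) {
  tibble::tibble(
    map50 = x$map50, map75 = x$map75, map50_95 = x$map50_95
  )
}

#' Evaluate detection files against ground-truth files
#'
#' Reads YOLO-dialect label folders (detections carry a sixth confidence
#' token) and runs [map_suite()]. File stems are the image references.
#'
#' @param det_dir,gt_dir Folders of `.txt` files.
#' @param thresholds IOU thresholds.
#' @return A `map_eval` object.
#' @export
evaluate_yolo_dirs <- function(det_dir, gt_dir,
                               thresholds = seq(0.5, 0.95, by = 0.05)) {
  read_dir <- function(dir) {
    files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
    dplyr::bind_rows(lapply(files, read_annotations))
  }
  dets <- read_dir(det_dir)
  if (nrow(dets) > 0 && !"score" %in% names(dets)) {
    dets$score <- 1
  }
  map_suite(dets, read_dir(gt_dir), thresholds = thresholds)
}

#' Write an evaluation result as JSON plus a per-class CSV
#'
#' The CSV is shaped like a per-class results table: one row per class
#' with its annotation count and AP at each threshold.
#'
#' @param result A `map_eval` object.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_eval_result <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        map50 = result$map50, map75 = result$map75,
        map50_95 = result$map50_95,
        per_threshold = result$per_threshold
      ),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  if (!is.null(csv_path)) {
    wide <- tidyr::pivot_wider(
      result$per_class,
      names_from = "iou_thresh", values_from = "ap", names_prefix = "ap_"
    )
    utils::write.csv(wide, csv_path, row.names = FALSE)
  }
  invisible(result)
}
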