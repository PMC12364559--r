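#' Augmentation configurations
#'
#' A configuration is the full tuning tuple for one augmented copy of a
#' dataset: the motion method, its parameters, and the augmentation mode.
#' Fields irrelevant to a method are `NA` (and supplying them is an
#' error), so a config tibble is always unambiguous about what was run.
#'
#' @param method `"raw"` (unmodified images), `"fd"` (three-frame
#'   differencing), `"bs_fd"` (background subtraction via frame
#'   averaging), `"bs_knn"` (KNN foreground mask) or `"flow"` (optical
#'   flow).
#' @param approach `"FD_a"` or `"FD_d"` (fd only).
#' @param delta_t Frame distance (fd/flow), >= 1.
#' @param upsilon Difference scaling (fd/bs_fd), >= 0.
#' @param n_b,delta_tb Background frame count and spacing (bs_fd only).
#' @param mode Augmentation mode: `"all"`, `"red"` or `"pca"`.
#' @param estimator Flow estimator id (flow only).
#' @param seed Integer seed (frame sampling for PCA, any stochastic
#'   estimator).
#'
#' @return A one-row tibble with one column per field.
#' @export
#' @examples
#' augmentation_config("fd", approach = "FD_d", delta_t = 4, upsilon = 15,
#'                     mode = "pca")
augmentation_config <- function(method = c("raw", "fd", "bs_fd", "bs_knn", "flow"),
                                approach = NULL, delta_t = NULL,
                                upsilon = NULL, n_b = NULL, delta_tb = NULL,
                                mode = NULL, estimator = NULL, seed = 1L) {
  method <- match.arg(method)
  allowed <- switch(method,
    raw = character(),
    fd = c("approach", "delta_t", "upsilon", "mode"),
    bs_fd = c("upsilon", "n_b", "delta_tb", "mode"),
    bs_knn = c("mode"),
    flow = c("delta_t", "estimator", "mode")
  )
  given <- list(approach = approach, delta_t = delta_t, upsilon = upsilon,
                n_b = n_b, delta_tb = delta_tb, mode = mode,
                estimator = estimator)
  extra <- names(given)[!vapply(given, is.null, logical(1))]
  extra <- setdiff(extra, allowed)
  if (length(extra) > 0) {
    abort(sprintf(
      "field(s) %s are not applicable to method '%s'.",
      paste(extra, collapse = ", "), method
    ), class = "motionaug_config_error")
  }
  defaults <- list(approach = "FD_a", delta_t = 1, upsilon = 1,
                   n_b = 10, delta_tb = 1, mode = "all",
                   estimator = "block_match")
  val <- function(f) {
    if (!f %in% allowed) return(NA)
    given[[f]] %||% defaults[[f]]
  }
  cfg <- tibble::tibble(
    method = method,
    approach = as.character(val("approach")),
    delta_t = as.numeric(val("delta_t")),
    upsilon = as.numeric(val("upsilon")),
    n_b = as.numeric(val("n_b")),
    delta_tb = as.numeric(val("delta_tb")),
    mode = as.character(val("mode")),
    estimator = as.character(val("estimator")),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ok_mode <- is.na(cfg$mode) | cfg$mode %in% c("all", "red", "pca")
  ok_app <- is.na(cfg$approach) | cfg$approach %in% c("FD_a", "FD_d")
  ok_dt <- is.na(cfg$delta_t) | cfg$delta_t >= 1
  ok_up <- is.na(cfg$upsilon) | cfg$upsilon >= 0
  if (!all(ok_mode & ok_app & ok_dt & ok_up)) {
    abort("invalid configuration values (mode/approach/delta_t/upsilon).",
          class = "motionaug_config_error")
  }
  invisible(cfg)
}

#' Expand a tuning grid into configurations
#'
#' Takes candidate values per field and returns the Cartesian product
#' restricted to valid method/field combinations (fields that do not
#' apply to a method are dropped before the product, so e.g. `raw`
#' contributes exactly one config regardless of the motion-parameter
#' candidates). Order is deterministic: methods in the given order, then
#' fields varying fastest from the right.
#'
#' The default candidate ranges follow the values that tuning on real
#' monitoring data has favoured: small `delta_t` (1) with `upsilon = 1`
#' for burst data, larger `delta_t` (4-5, up to 100+ background spacing)
#' with `upsilon = 15` for video, both differencing approaches, and all
#' three augmentation modes.
#'
#' @param methods Methods to include.
#' @param approach,delta_t,upsilon,n_b,delta_tb,mode,estimator Candidate
#'   values per field.
#' @param seed Seed stored on every config.
#' @return A config tibble, one row per configuration.
#' @export
#' @examples
#' nrow(expand_augmentation_grid(methods = "fd", delta_t = c(1, 4),
#'                               upsilon = c(1, 15), mode = "pca"))
expand_augmentation_grid <- function(methods = c("raw", "fd", "bs_fd", "flow"),
                                     approach = c("FD_a", "FD_d"),
                                     delta_t = c(1, 4),
                                     upsilon = c(1, 15),
                                     n_b = 10, delta_tb = 1,
                                     mode = c("all", "red", "pca"),
                                     estimator = "block_match",
                                     seed = 1L) {
  if (length(methods) == 0) {
    abort("the tuning grid is empty: no methods given.")
  }
  fields <- list(approach = approach, delta_t = delta_t, upsilon = upsilon,
                 n_b = n_b, delta_tb = delta_tb, mode = mode,
                 estimator = estimator)
  per_method <- lapply(methods, function(m) {
    allowed <- switch(m,
      raw = character(),
      fd = c("approach", "delta_t", "upsilon", "mode"),
      bs_fd = c("upsilon", "n_b", "delta_tb", "mode"),
      bs_knn = c("mode"),
      flow = c("delta_t", "estimator", "mode")
    )
    if (is.null(allowed)) {
      abort(sprintf("unknown method '%s' in grid.", m))
    }
    use <- fields[allowed]
    if (any(lengths(use) == 0)) {
      abort(sprintf("empty candidate list for method '%s'.", m))
    }
    grid <- if (length(use) == 0) {
      tibble::tibble(.rows = 1)
    } else {
      do.call(tidyr::expand_grid, use)
    }
    for (f in names(fields)) {
      if (!f %in% names(grid)) grid[[f]] <- NA
    }
    dplyr::mutate(grid, method = m, seed = as.integer(seed))
  })
  out <- dplyr::bind_rows(per_method)
  out <- dplyr::select(
    out, "method", "approach", "delta_t", "upsilon",
    "n_b", "delta_tb", "mode", "estimator", "seed"
  )
  out <- dplyr::mutate(
    out,
    approach = as.character(.data$approach),
    mode = as.character(.data$mode),
    estimator = as.character(.data$estimator),
    delta_t = as.numeric(.data$delta_t),
    upsilon = as.numeric(.data$upsilon),
    n_b = as.numeric(.data$n_b),
    delta_tb = as.numeric(.data$delta_tb)
  )
  validate_config(out)
  out
}

#' Select the best configuration per method on the validation split
#'
#' Tuning records are config rows plus a `split` column and metric
#' columns (`map50`, `map75`, `map50_95`), typically produced by an
#' external detector run on each augmented dataset copy. Selection uses
#' validation records only — test metrics are reserved for final
#' reporting, and the returned object's `splits_consulted` attribute
#' records that guarantee so it can be audited.
#'
#' Ties on the criterion break towards the simpler config: smaller
#' `delta_t`, then smaller `upsilon`, then mode order all < red < pca.
#'
#' With `two_stage = TRUE` (mirroring a tune-motion-first workflow),
#' motion parameters are first chosen among records with
#' `mode == stage1_mode`, then the mode is chosen among records with the
#' winning motion parameters frozen.
#'
#' @param records Tuning-record tibble.
#' @param metric Criterion column; default `"map50"`.
#' @param two_stage Use the two-stage selection described above.
#' @param stage1_mode Mode held fixed during stage 1.
#' @return One best config row per method (metric columns retained),
#'   with attribute `splits_consulted = "val"`.
#' @export
select_best <- function(records, metric = "map50", two_stage = FALSE,
                        stage1_mode = "all") {
  if (!metric %in% names(records)) {
    abort(sprintf("metric column '%s' is missing from the records.", metric))
  }
  val <- dplyr::filter(records, .data$split == "val")
  missing <- setdiff(unique(records$method), unique(val$method))
  if (nrow(val) == 0 || length(missing) > 0) {
    abort(sprintf(
      "no validation records for method(s): %s.",
      paste(if (nrow(val) == 0) unique(records$method) else missing,
            collapse = ", ")
    ))
  }
  mode_rank <- function(m) match(m, c("all", "red", "pca"))
  pick <- function(tbl) {
    tbl <- dplyr::arrange(
      tbl, dplyr::desc(.data[[metric]]),
      dplyr::coalesce(.data$delta_t, -Inf),
      dplyr::coalesce(.data$upsilon, -Inf),
      dplyr::coalesce(mode_rank(.data$mode), 0)
    )
    tbl[1, ]
  }
  best <- dplyr::group_modify(
    dplyr::group_by(val, .data$method),
    function(tbl, key) {
      if (!two_stage || key$method == "raw") {
        return(pick(tbl))
      }
      stage1 <- dplyr::filter(tbl, .data$mode == stage1_mode)
      if (nrow(stage1) == 0) stage1 <- tbl
      win <- pick(stage1)
      frozen <- dplyr::filter(
        tbl,
        (is.na(.data$delta_t) & is.na(win$delta_t)) |
          .data$delta_t %in% win$delta_t,
        (is.na(.data$upsilon) & is.na(win$upsilon)) |
          .data$upsilon %in% win$upsilon,
        (is.na(.data$approach) & is.na(win$approach)) |
          .data$approach %in% win$approach
      )
      pick(frozen)
    }
  )
  best <- dplyr::ungroup(best)
  attr(best, "splits_consulted") <- "val"
  best
}

#' Format tuning records as comparison tables
#'
#' Produces the per-method x metric comparison on the test split: a wide
#' tibble (one row per method, one column per metric) and, when `path`
#' is given, a Markdown rendering with the best value per metric column
#' bolded.
#'
#' @param records Tuning-record tibble (test-split rows are used).
#' @param metrics Metric columns to tabulate.
#' @param path Optional output file for the Markdown table.
#' @return The wide tibble, invisibly when writing; the `best_per_metric`
#'   attribute names the winning method per column.
#' @export
report_tuning <- function(records, metrics = c("map50", "map75", "map50_95"),
                          path = NULL) {
  test <- dplyr::filter(records, .data$split == "test")
  if (nrow(test) == 0) {
    abort("no test-split records to report.")
  }
  tbl <- dplyr::summarise(
    dplyr::group_by(test, .data$method),
    dplyr::across(dplyr::all_of(metrics), max),
    .groups = "drop"
  )
  best <- vapply(metrics, function(m) tbl$method[which.max(tbl[[m]])],
                 character(1))
  attr(tbl, "best_per_metric") <- best
  if (!is.null(path)) {
    fmt_col <- function(m) {
      v <- sprintf("%.3f", tbl[[m]])
      v[which.max(tbl[[m]])] <- paste0("**", v[which.max(tbl[[m]])], "**")
      v
    }
    cells <- vapply(metrics, fmt_col, character(nrow(tbl)))
    cells <- matrix(cells, nrow = nrow(tbl))
    lines <- c(
      paste0("| Method | ", paste(metrics, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(metrics) + 1), collapse = "|"), "|"),
      vapply(seq_len(nrow(tbl)), function(i) {
        paste0("| ", tbl$method[i], " | ",
               paste(cells[i, ], collapse = " | "), " |")
      }, character(1))
    )
    writeLines(lines, path)
    return(invisible(tbl))
  }
  tbl
}
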