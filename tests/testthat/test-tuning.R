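test_that("the grid expands to the expected cartesian counts", {
  g <- expand_augmentation_grid(
    methods = "fd", approach = c("FD_a", "FD_d"),
    delta_t = c(1, 4), upsilon = c(1, 15), mode = "pca"
  )
  expect_equal(nrow(g), 8)
  expect_true(all(g$method == "fd"))
  expect_true(all(is.na(g$n_b)))

  raw <- expand_augmentation_grid(methods = "raw")
  expect_equal(nrow(raw), 1)
  expect_true(all(is.na(raw$delta_t)))
  expect_true(all(is.na(raw$mode)))

  both <- expand_augmentation_grid(
    methods = c("raw", "fd"), approach = "FD_a",
    delta_t = 1, upsilon = c(1, 15), mode = c("all", "red")
  )
  expect_equal(nrow(both), 1 + 4)
  # deterministic order
  expect_identical(both, expand_augmentation_grid(
    methods = c("raw", "fd"), approach = "FD_a",
    delta_t = 1, upsilon = c(1, 15), mode = c("all", "red")
  ))
})

test_that("invalid method/field combinations are rejected", {
  expect_error(augmentation_config("raw", upsilon = 2),
               class = "motionaug_config_error")
  expect_error(augmentation_config("flow", upsilon = 2),
               class = "motionaug_config_error")
  expect_error(augmentation_config("fd", delta_t = 0),
               class = "motionaug_config_error")
  expect_error(expand_augmentation_grid(methods = character()), "empty")
  expect_error(expand_augmentation_grid(methods = "fd", delta_t = numeric()),
               "empty candidate")
})

toy_records <- function() {
  g <- expand_augmentation_grid(
    methods = "fd", approach = c("FD_a", "FD_d"),
    delta_t = c(1, 4), upsilon = c(1, 15), mode = c("all", "pca")
  )
  val <- dplyr::mutate(g, split = "val",
                       map50 = 0.60, map75 = 0.40, map50_95 = 0.35)
  best_row <- val$approach == "FD_d" & val$delta_t == 4 &
    val$upsilon == 15 & val$mode == "pca"
  val$map50[best_row] <- 0.75
  test <- dplyr::mutate(g, split = "test",
                        map50 = 0.99, map75 = 0.9, map50_95 = 0.9)
  dplyr::bind_rows(val, test)
}

test_that("select_best picks the validation argmax per method", {
  best <- select_best(toy_records())
  expect_equal(nrow(best), 1)
  expect_equal(best$approach, "FD_d")
  expect_equal(best$delta_t, 4)
  expect_equal(best$upsilon, 15)
  expect_equal(best$mode, "pca")
  expect_equal(best$map50, 0.75)
})

test_that("select_best never consults test metrics (leakage guard)", {
  rec <- toy_records()
  best <- select_best(rec)
  expect_identical(attr(best, "splits_consulted"), "val")
  # corrupting every test metric must not change the selection
  poisoned <- dplyr::mutate(
    rec,
    map50 = ifelse(split == "test", runif(dplyr::n()), map50)
  )
  best2 <- select_best(poisoned)
  expect_equal(best2$map50, best$map50)
  expect_identical(best2[, c("approach", "delta_t", "upsilon", "mode")],
                   best[, c("approach", "delta_t", "upsilon", "mode")])
  # a single record is its own argmax
  one <- rec[rec$split == "val", ][1, ]
  expect_equal(select_best(one)$map50, one$map50)
  # absent validation metrics are an error naming the method
  expect_error(select_best(rec[rec$split == "test", ]), "fd")
})

test_that("exact ties break towards smaller delta_t, upsilon, mode order", {
  g <- expand_augmentation_grid(
    methods = "fd", approach = "FD_a", delta_t = c(1, 4),
    upsilon = c(1, 15), mode = c("all", "pca")
  )
  rec <- dplyr::mutate(g, split = "val",
                       map50 = 0.5, map75 = 0.5, map50_95 = 0.5)
  best <- select_best(rec)
  expect_equal(best$delta_t, 1)
  expect_equal(best$upsilon, 1)
  expect_equal(best$mode, "all")
})

test_that("two-stage selection freezes motion parameters before the mode", {
  g <- expand_augmentation_grid(
    methods = "fd", approach = "FD_a", delta_t = c(1, 4),
    upsilon = 1, mode = c("all", "red", "pca")
  )
  rec <- dplyr::mutate(g, split = "val", map75 = 0, map50_95 = 0)
  # stage 1 (mode == all): delta_t = 4 wins; stage 2: red wins at delta_t 4.
  rec$map50 <- unname(c(all_1 = 0.5, all_4 = 0.6, red_1 = 0.9, red_4 = 0.7,
                        pca_1 = 0.1, pca_4 = 0.2)[
    paste(rec$mode, rec$delta_t, sep = "_")])
  best <- select_best(rec, two_stage = TRUE)
  expect_equal(best$delta_t, 4)
  expect_equal(best$mode, "red")
  # single-stage full grid would instead take the global argmax
  expect_equal(select_best(rec)$map50, 0.9)
})

test_that("report_tuning tabulates test metrics with best flagged", {
  g <- dplyr::bind_rows(
    expand_augmentation_grid(methods = "raw"),
    expand_augmentation_grid(methods = "fd", approach = "FD_a",
                             delta_t = 1, upsilon = 1, mode = "all")
  )
  rec <- dplyr::mutate(g, split = "test",
                       map50 = c(0.9, 0.7), map75 = c(0.5, 0.8),
                       map50_95 = c(0.4, 0.6))
  tbl <- report_tuning(rec)
  expect_equal(nrow(tbl), 2)
  best <- attr(tbl, "best_per_metric")
  expect_equal(unname(best["map50"]), "raw")
  expect_equal(unname(best["map75"]), "fd")
  md <- withr::local_tempfile(fileext = ".md")
  report_tuning(rec, path = md)
  lines <- readLines(md)
  expect_match(lines[1], "map50")
  expect_true(any(grepl("\\*\\*0.900\\*\\*", lines)))
  expect_error(report_tuning(dplyr::mutate(rec, split = "val")), "test-split")
})

test_that("the cli dispatches simulate and eval end to end", {
  root <- withr::local_tempdir()
  ds <- file.path(root, "ds")
  expect_output(
    motionaug_cli(c("simulate", "--out", ds, "--seed", "3", "--frames", "6")),
    "wrote dataset"
  )
  expect_true(file.exists(file.path(ds, "manifest.yaml")))
  man <- read_manifest(file.path(ds, "manifest.yaml"))
  expect_equal(nrow(man$entries), 6)

  gt_dir <- file.path(root, "gt")
  dir.create(gt_dir)
  gt <- tibble::tibble(image_ref = "a", class_id = 0L,
                       cx = 0.5, cy = 0.5, bw = 0.2, bh = 0.2)
  write_annotations(gt, file.path(gt_dir, "a.txt"))
  det_dir <- file.path(root, "det")
  dir.create(det_dir)
  write_annotations(dplyr::mutate(gt, score = 0.9),
                    file.path(det_dir, "a.txt"))
  out_json <- file.path(root, "eval.json")
  expect_output(
    motionaug_cli(c("eval", "--detections", det_dir,
                    "--ground-truth", gt_dir, "--out", out_json)),
    "mAP@50"
  )
  expect_equal(jsonlite::read_json(out_json)$map50, 1.0)
  expect_error(motionaug_cli(c("augment")), "manifest")
})

test_that("autoplot methods return ggplot objects", {
  s <- random_seq(n = 5, seed = 2)
  expect_s3_class(autoplot(frame_difference_abs(s, 3, 1, 5)), "ggplot")
  pair <- rigid_shift_pair(shift = 2)
  fl <- flow_field(frame_sequence(list(pair$a, pair$b, pair$a)), 1, radius = 3)
  expect_s3_class(autoplot(fl), "ggplot")
  gt <- tibble::tibble(image_ref = "a", class_id = 0L,
                       cx = 0.5, cy = 0.5, bw = 0.2, bh = 0.2)
  expect_s3_class(autoplot(map_suite(dplyr::mutate(gt, score = 1), gt)),
                  "ggplot")
})
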