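aug_fixture <- function(seed = 3) {
  out <- generate_sequence(scene_spec(
    background = "textured", n_frames = 5, noise_sd = 0.01,
    objects = list(object_spec(position = c(8, 8), trajectory = c(2, 0))),
    seed = seed
  ))
  list(
    seq = out$sequence,
    frame = get_frame(out$sequence, 3),
    m3 = frame_difference_dir(out$sequence, 3, 1, 5),
    m1 = collapse_layers(frame_difference_abs(out$sequence, 3, 1, 5))
  )
}

test_that("replace-all returns the motion map verbatim with provenance", {
  fx <- aug_fixture()
  a <- augment_replace_all(fx$frame, fx$m3)
  expect_identical(a$values, fx$m3$values)
  expect_equal(a$mode, "all")
  expect_equal(a$provenance$method, "fd_d")
  expect_equal(a$provenance$params$delta_t, 1)
  expect_equal(a$provenance$params$upsilon, 5)
  expect_error(augment_replace_all(fx$frame, fx$m1), "3-layer")
})

test_that("replace-red swaps only the red layer", {
  fx <- aug_fixture()
  a <- augment_replace_red(fx$frame, fx$m1)
  expect_identical(a$values[, , 1], fx$m1$values[, , 1])
  expect_identical(a$values[, , 2], fx$frame[, , 2])
  expect_identical(a$values[, , 3], fx$frame[, , 3])
  # mutating the motion map never changes green/blue
  m_alt <- fx$m1
  m_alt$values <- 1 - m_alt$values
  b <- augment_replace_red(fx$frame, m_alt)
  expect_identical(b$values[, , 2:3], a$values[, , 2:3])
  # zero motion zeroes the red channel
  zero <- motion_map(array(0, dim = c(dim(fx$frame)[1:2], 1L)), "fd_a", list())
  z <- augment_replace_red(fx$frame, zero)
  expect_true(all(z$values[, , 1] == 0))
})

test_that("pca augmentation composes motion and compressed colour", {
  fx <- aug_fixture()
  model <- fit_pca_color(fx$seq$frames, seed = 4)
  a <- augment_pca(fx$frame, fx$m1, model)
  comp <- apply_pca_color(model, fx$frame)
  expect_identical(a$values[, , 1], fx$m1$values[, , 1])
  expect_identical(a$values[, , 2], comp[, , 1])
  expect_identical(a$values[, , 3], comp[, , 2])
  # swapping p1/p2 in the model swaps green and blue
  swapped <- model
  swapped$components <- model$components[, 2:1]
  swapped$whitening_scale <- model$whitening_scale[2:1]
  swapped$range_offset <- model$range_offset[2:1]
  swapped$range_scale <- model$range_scale[2:1]
  b <- augment_pca(fx$frame, fx$m1, swapped)
  expect_identical(b$values[, , 2], a$values[, , 3])
  expect_identical(b$values[, , 3], a$values[, , 2])
  expect_error(augment_pca(fx$frame, fx$m1, list()), "pca_color_model")
})

make_dataset <- function(dir, n_frames = 6) {
  spec <- scene_spec(
    background = "textured", n_frames = n_frames, noise_sd = 0.01,
    objects = list(object_spec(position = c(4, 4), trajectory = c(2, 1))),
    seed = 17
  )
  write_scene_dataset(
    spec, dir,
    split = rep(c("train", "val", "test"), length.out = n_frames)
  )
  read_manifest(file.path(dir, "manifest.yaml"))
}

test_that("raw config copies images and labels byte-identically", {
  root <- withr::local_tempdir()
  out <- file.path(root, "aug")
  man <- make_dataset(file.path(root, "data"))
  cfg <- augmentation_config("raw")
  res <- augment_dataset(man, cfg, out)
  expect_true(all(res$written$ok))
  e <- man$entries[1, ]
  src <- file.path(man$root, "sequences", e$sequence,
                   sprintf("frame_%06d.png", e$frame))
  dst <- file.path(out, "images", e$split, paste0(e$image, ".png"))
  expect_identical(readBin(src, "raw", file.size(src)),
                   readBin(dst, "raw", file.size(dst)))
})

test_that("label files pass through unchanged for every mode", {
  root <- withr::local_tempdir()
  man <- make_dataset(file.path(root, "data"))
  for (mode in c("all", "red", "pca")) {
    out <- file.path(root, paste0("aug_", mode))
    cfg <- augmentation_config("fd", approach = "FD_a", delta_t = 1,
                               upsilon = 5, mode = mode)
    res <- augment_dataset(man, cfg, out)
    expect_true(all(res$written$ok))
    for (i in seq_len(nrow(man$entries))) {
      e <- man$entries[i, ]
      src <- file.path(man$root, "labels", paste0(e$image, ".txt"))
      dst <- file.path(out, "labels", e$split, paste0(e$image, ".txt"))
      expect_identical(readLines(dst), readLines(src))
    }
  }
})

test_that("augmenting a dataset twice is byte-identical", {
  root <- withr::local_tempdir()
  man <- make_dataset(file.path(root, "data"))
  cfg <- augmentation_config("bs_fd", n_b = 2, delta_tb = 1,
                             upsilon = 5, mode = "pca", seed = 11)
  res1 <- augment_dataset(man, cfg, file.path(root, "a"))
  res2 <- augment_dataset(man, cfg, file.path(root, "b"))
  for (i in seq_len(nrow(res1$written))) {
    f1 <- res1$written$path[i]
    f2 <- res2$written$path[i]
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("the pca model is fitted on train frames only (audited)", {
  root <- withr::local_tempdir()
  man <- make_dataset(file.path(root, "data"))
  cfg <- augmentation_config("fd", delta_t = 1, upsilon = 5, mode = "pca")
  res <- augment_dataset(man, cfg, file.path(root, "aug"))
  log <- lapply(readLines(res$run_log), jsonlite::fromJSON)
  fit <- Filter(function(x) x$event == "pca_fit", log)[[1]]
  train_ids <- man$entries$image[man$entries$split == "train"]
  expect_true(all(fit$frame_ids %in% train_ids))
  expect_equal(fit$split, "train")
  model <- read_pca_model(res$pca_model)
  expect_true(all(model$frame_ids %in% train_ids))
})

test_that("unresolvable frames are collected, not fatal, unless strict", {
  root <- withr::local_tempdir()
  man <- make_dataset(file.path(root, "data"))
  man$entries$frame[2] <- 99L
  cfg <- augmentation_config("fd", delta_t = 1, upsilon = 5, mode = "all")
  res <- augment_dataset(man, cfg, file.path(root, "aug"))
  expect_equal(sum(!res$written$ok), 1)
  expect_length(res$errors, 1)
  expect_match(res$errors, "not loaded")
  expect_error(
    augment_dataset(man, cfg, file.path(root, "aug2"), strict = TRUE),
    class = "motionaug_missing_frame"
  )
})
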