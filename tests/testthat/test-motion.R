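# Frozen hand-arithmetic cases for the differencing measures; each is
# also cross-checked against the scalar loop oracle.

test_that("absolute differencing reproduces the single-pixel arithmetic", {
  s <- scalar_seq(c(0.2, 0.5, 0.7))
  expect_equal(frame_difference_abs(s, 2, 1, 1)$values[1, 1, 1], 0.25)
  expect_equal(frame_difference_abs(s, 2, 1, 15)$values[1, 1, 1], 1.0)
  expect_equal(frame_difference_abs(s, 2, 1, 1)$values,
               oracle_fd_abs(s, 2, 1, 1))
})

test_that("directional differencing centres at 0.5 and signs correctly", {
  up <- scalar_seq(c(0.2, 0.5, 0.7))
  expect_equal(frame_difference_dir(up, 2, 1, 1)$values[1, 1, 1], 0.7)
  down <- scalar_seq(c(0.9, 0.5, 0.1))
  expect_equal(frame_difference_dir(down, 2, 1, 1)$values[1, 1, 1], 0.2)
  expect_equal(frame_difference_dir(down, 2, 1, 1)$values,
               oracle_fd_dir(down, 2, 1, 1))
})

test_that("background averaging and subtraction reproduce the hand values", {
  s <- scalar_seq(c(0.2, 0.4, 0.8))
  expect_equal(background_frame(s, 3, n_b = 2, delta_tb = 1)[1, 1, 1], 0.3)
  expect_equal(background_frame(s, 3, n_b = 1, delta_tb = 1),
               s$frames[[2]])
  expect_equal(
    background_subtract_fd(s, 3, n_b = 2, delta_tb = 1, upsilon = 1)$values[1, 1, 1],
    0.75
  )
  expect_equal(
    background_subtract_fd(s, 3, n_b = 2, delta_tb = 1, upsilon = 15)$values[1, 1, 1],
    1.0
  )
})

test_that("static sequences yield the exact resting levels", {
  f <- array(0.37, dim = c(6, 6, 3))
  s <- frame_sequence(rep(list(f), 8))
  expect_true(all(frame_difference_abs(s, 4, 2, 15)$values == 0))
  expect_true(all(frame_difference_dir(s, 4, 2, 15)$values == 0.5))
  expect_true(all(
    background_subtract_fd(s, 8, n_b = 5, delta_tb = 1, upsilon = 15)$values == 0.5
  ))
  expect_true(all(
    background_subtract_knn(s, 8, history = 5)$values == 0
  ))
})

test_that("every differencing operator matches its scalar loop oracle", {
  for (seed in 1:12) {
    s <- random_seq(n = 7, h = 8, w = 8, seed = seed)
    dt <- 1 + seed %% 2
    up <- c(1, 3, 15)[1 + seed %% 3]
    expect_lt(max(abs(frame_difference_abs(s, 4, dt, up)$values -
                        oracle_fd_abs(s, 4, dt, up))), 1e-12)
    expect_lt(max(abs(frame_difference_dir(s, 4, dt, up)$values -
                        oracle_fd_dir(s, 4, dt, up))), 1e-12)
    expect_lt(max(abs(background_frame(s, 7, n_b = 3, delta_tb = 2) -
                        oracle_background(s, 7, 3, 2))), 1e-12)
    expect_lt(max(abs(background_subtract_fd(s, 7, 3, 2, up)$values -
                        oracle_bs_fd(s, 7, 3, 2, up))), 1e-12)
    knn <- background_subtract_knn(s, 7, history = 5, k = 3,
                                   dist_threshold = 0.3)
    expect_identical(knn$values[, , 1], oracle_knn(s, 7, 5, 3, 0.3))
  }
})

test_that("scaling monotonicity: larger upsilon never shrinks the signal", {
  s <- random_seq(n = 5, h = 8, w = 8, seed = 42)
  ups <- c(0.5, 1, 2, 5, 15)
  dev_a <- vapply(ups, function(u) {
    mean(abs(frame_difference_abs(s, 3, 1, u)$values - 0))
  }, numeric(1))
  dev_d <- vapply(ups, function(u) {
    mean(abs(frame_difference_dir(s, 3, 1, u)$values - 0.5))
  }, numeric(1))
  dev_b <- vapply(ups, function(u) {
    mean(abs(background_subtract_fd(s, 5, 3, 1, u)$values - 0.5))
  }, numeric(1))
  expect_true(all(diff(dev_a) >= 0))
  expect_true(all(diff(dev_d) >= 0))
  expect_true(all(diff(dev_b) >= 0))
})

test_that("the KNN mask is binary and flags an abrupt pixel jump", {
  frames <- rep(list(array(0, dim = c(3, 3, 3))), 6)
  jump <- array(0, dim = c(3, 3, 3))
  jump[2, 2, ] <- 1
  frames[[6]] <- jump
  s <- frame_sequence(frames)
  m <- background_subtract_knn(s, 6, history = 5, k = 3,
                               dist_threshold = 0.1)
  expect_setequal(unique(as.vector(m$values)), c(0, 1))
  expect_equal(m$values[2, 2, 1], 1)
  expect_equal(sum(m$values), 1)
})

test_that("boundary policy clamps by default and errors when strict", {
  s <- random_seq(n = 4, h = 4, w = 4, seed = 6)
  expect_error(frame_difference_abs(s, 1, 1, 1, boundary = "strict"),
               class = "motionaug_missing_frame")
  expect_error(background_frame(s, 2, n_b = 5, delta_tb = 1,
                                boundary = "strict"),
               class = "motionaug_missing_frame")
  expect_error(background_subtract_knn(s, 3, history = 10,
                                       boundary = "strict"),
               class = "motionaug_missing_frame")
  # clamped first-frame call reuses frame 1 as its own left neighbour
  m <- frame_difference_abs(s, 1, 1, 1)
  ref <- clamp01(0.5 * (abs(s$frames[[1]] - s$frames[[1]]) +
                          abs(s$frames[[1]] - s$frames[[2]])))
  expect_equal(m$values, ref)
})

test_that("collapse_layers averages the three layers per pixel", {
  vals <- array(0, dim = c(1, 1, 3))
  vals[1, 1, ] <- c(0.2, 0.4, 0.6)
  m <- motion_map(vals, "fd_a", list())
  expect_equal(collapse_layers(m)$values[1, 1, 1], 0.4)
  s <- random_seq(n = 5, seed = 13)
  m2 <- frame_difference_dir(s, 3, 1, 2)
  expect_lt(max(abs(collapse_layers(m2)$values[, , 1] -
                      oracle_collapse(m2$values))), 1e-12)
  expect_error(collapse_layers(collapse_layers(m2)), "3-layer")
})

test_that("motion maps persist as PNG plus sidecar and round-trip", {
  dir <- withr::local_tempdir()
  s <- random_seq(n = 5, seed = 21)
  m <- frame_difference_abs(s, 3, 1, 5)
  # quantise to the 8-bit grid so the PNG round trip is exact
  m$values <- round(m$values * 255) / 255
  p <- file.path(dir, "m.png")
  write_motion_map(m, p)
  back <- read_motion_map(p)
  expect_equal(back$values, m$values)
  expect_equal(back$method, "fd_a")
  expect_equal(back$params$upsilon, 5)
  m1 <- collapse_layers(m)
  m1$values <- round(m1$values * 255) / 255
  write_motion_map(m1, p)
  expect_equal(dim(read_motion_map(p)$values)[3], 1L)
})

test_that("synthetic recovery: thresholded FD_a finds the moving square", {
  ious <- vapply(1:5, fd_recovery_iou, numeric(1))
  expect_true(all(ious >= 0.9))
})
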