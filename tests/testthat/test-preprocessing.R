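test_that("HU windowing clamps and rescales linearly", {
  w <- window_spec(-100, 400)
  img <- matrix(c(-200, 400, 150, -100), 2, 2)
  out <- window_hu(img, w)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)
  expect_equal(out[1, 2], 0.5)
  expect_equal(out[2, 2], 0)
})

test_that("windowed output lies in [0,1] and re-windowing with the unit window is the identity", {
  set.seed(3)
  img <- matrix(rnorm(64 * 64, mean = 50, sd = 400), 64, 64)
  w <- window_spec(-100, 400)
  y <- window_hu(img, w)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(window_hu(y, window_spec(0, 1)), y)
})

test_that("windowing validates its inputs", {
  expect_error(window_spec(400, -100), "window")
  img <- matrix(1, 2, 2); img[1] <- NA
  expect_error(window_hu(img), "finite")
})

test_that("resizing: bilinear preserves constants, nearest preserves binarity", {
  img <- matrix(0.3, 512, 512)
  out <- resize_to_grid(img, 224)
  expect_equal(dim(out), c(224, 224))
  expect_equal(range(out), c(0.3, 0.3), tolerance = 1e-12)
  mask <- matrix(0, 512, 512); mask[100:300, 150:350] <- 1
  mout <- resize_to_grid(mask, 224, is_mask = TRUE)
  expect_true(all(mout %in% c(0, 1)))
  ones <- matrix(1, 512, 512)
  expect_true(all(resize_to_grid(ones, 224, is_mask = TRUE) == 1))
  expect_error(resize_to_grid(matrix(0, 4, 6), 2), "square")
})

test_that("dataset splitting is a seeded partition with round(ratio*n) training ids", {
  ids <- sprintf("s%02d", 1:10)
  sp <- split_dataset(ids, 0.8, seed = 3)
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 2)
  expect_setequal(c(sp$train_ids, sp$val_ids), ids)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  sp2 <- split_dataset(ids, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train_ids, split_dataset(ids, 0.8, seed = 4)$train_ids))
  # partition property across sizes and ratios
  for (n in c(5, 23, 100)) for (ratio in c(0.2, 0.5, 0.8)) {
    idv <- as.character(seq_len(n))
    s <- split_dataset(idv, ratio, seed = n)
    expect_length(s$train_ids, round(ratio * n))
    expect_setequal(c(s$train_ids, s$val_ids), idv)
  }
  expect_error(split_dataset(character(0)), "non-empty")
  expect_error(split_dataset(ids, 1.2), "ratio")
  expect_error(split_dataset(c("a", "b"), 0.99), "ratio")
})

test_that("contour overlay colors exactly the boundary set", {
  img <- matrix(0.5, 5, 5)
  mask <- matrix(0, 5, 5); mask[2:4, 2:4] <- 1
  out <- overlay_contour(img, mask, c(1, 0, 0))
  changed <- out[, , 1] != 0.5 | out[, , 2] != 0.5 | out[, , 3] != 0.5
  expect_equal(sum(changed), 8)  # 3x3 square ring
  expect_true(all(out[, , 1][changed] == 1))
  expect_true(all(out[, , 2][changed] == 0))
  # empty mask: replication only
  out0 <- overlay_contour(img, matrix(0, 5, 5))
  expect_equal(out0[, , 1], img)
  expect_equal(out0[, , 3], img)
  # single-pixel mask: its erosion is empty, so exactly that pixel changes
  m1 <- matrix(0, 5, 5); m1[3, 3] <- 1
  out1 <- overlay_contour(img, m1, c(0, 1, 0))
  changed1 <- out1[, , 2] != 0.5
  expect_equal(which(changed1), which(m1 == 1))
  expect_error(overlay_contour(img, matrix(0, 4, 4)), "grid")
})

test_that("augmentation ops transform image and masks identically", {
  cfg <- phantom_config(image_size = 64, lesion_count_range = c(1L, 2L))
  s <- generate_phantom(cfg, seed = 8)
  # double horizontal flip is the identity
  s2 <- augment(s, c("hflip", "hflip"))
  expect_identical(s2$image, s$image)
  expect_identical(s2$liver_mask, s$liver_mask)
  # flips preserve lesion-within-liver nesting and binarity
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    sa <- augment(s, op)
    expect_true(all(sa$lesion_mask * (1 - sa$liver_mask) == 0), label = op)
    expect_true(all(sa$liver_mask %in% c(0, 1)), label = op)
    expect_identical(dim(sa$image), dim(s$image))
  }
  expect_error(augment(s, "shear"), "shear")
})

test_that("rot90 matches an explicit coordinate remap oracle", {
  m <- matrix(seq_len(12), 3, 4)
  s <- list(image = m, any_mask = (m %% 2 == 0) * 1)
  r <- augment(s, "rot90")
  # clockwise: out[i, j] == in[n - j + 1, i] for an n-row input
  n <- nrow(m)
  expect_equal(dim(r$image), c(4, 3))
  for (i in seq_len(4)) for (j in seq_len(3)) {
    expect_equal(r$image[i, j], m[n - j + 1, i])
  }
  # four quarter turns are the identity
  r4 <- augment(s, rep("rot90", 4))
  expect_identical(r4$image, m)
  # seeded application: a fixed seed selects a reproducible subset of ops
  a1 <- augment(s, c("hflip", "vflip"), seed = 21)
  a2 <- augment(s, c("hflip", "vflip"), seed = 21)
  expect_identical(a1, a2)
})
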