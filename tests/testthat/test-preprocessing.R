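# CT preprocessing chain: windowing, normalisation, CLAHE, 2.5D stacking,
# augmentation and the NIfTI round trip.

test_that("windowing clips exactly to [level - w/2, level + w/2] and is idempotent", {
  v <- array(c(-500, 300, 40, -60, 140), c(5, 1, 1))
  w <- window_clip(v)
  expect_equal(as.vector(w), c(-60, 140, 40, -60, 140))
  expect_identical(window_clip(w), w)
  expect_equal(range(window_clip(array(rnorm(1000, 0, 400), c(10, 10, 10)))),
               c(-60, 140))
  # non-default window
  expect_equal(as.vector(window_clip(v, width = 400, level = 0)),
               c(-200, 200, 40, -60, 140))
})

test_that("min-max normalisation maps the window bounds to [0, 1]", {
  expect_equal(minmax_normalize(-60), 0)
  expect_equal(minmax_normalize(140), 1)
  expect_equal(minmax_normalize(40), 0.5)
  x <- minmax_normalize(array(rnorm(500, 40, 200), c(10, 10, 5)))
  expect_true(all(x >= 0 & x <= 1))
})

test_that("windowing and normalisation commute with slice extraction", {
  set.seed(91)
  v <- array(rnorm(16 * 16 * 4, 40, 150), c(16, 16, 4))
  whole <- minmax_normalize(window_clip(v))
  for (i in 1:4) {
    slice <- matrix(v[, , i], 16)
    expect_equal(whole[, , i], minmax_normalize(window_clip(slice)),
                 ignore_attr = TRUE)
  }
})

test_that("CLAHE maps constants to constants and stays in [0, 1]", {
  const <- matrix(0.5, 64, 64)
  out <- clahe_equalize(const)
  expect_equal(max(out) - min(out), 0)

  set.seed(92)
  r <- clahe_equalize(matrix(runif(96 * 96), 96))
  expect_true(all(r >= 0 & r <= 1))

  # a low-contrast checkerboard gains (or keeps) contrast
  cb <- matrix(rep(c(0.45, 0.55), length.out = 96 * 96), 96)
  eq <- clahe_equalize(cb)
  expect_gte(max(eq) - min(eq), max(cb) - min(cb))
})

test_that("2.5D stacking replicates edges and builds nested binary targets", {
  set.seed(93)
  vol <- array(runif(8 * 8 * 5), c(8, 8, 5))
  lab <- array(0L, c(8, 8, 5))
  lab[3:5, 3:5, 2] <- 1L
  lab[4, 4, 2] <- 2L

  s0 <- stack_25d(vol, lab, 1)
  expect_equal(s0$image[, , 1], s0$image[, , 2])   # replicated lower edge
  expect_equal(s0$image[, , 3], vol[, , 2])
  s4 <- stack_25d(vol, lab, 5)
  expect_equal(s4$image[, , 2], s4$image[, , 3])   # replicated upper edge

  s <- stack_25d(vol, lab, 2)
  expect_identical(dim(s$image), c(8L, 8L, 3L))
  expect_identical(dim(s$target), c(8L, 8L, 2L))
  expect_true(all(s$target %in% c(0, 1)))
  # liver mask covers both label-1 and label-2 voxels
  expect_equal(sum(s$target[, , 1]), 9)
  expect_equal(sum(s$target[, , 2]), 1)
  expect_true(all(s$target[, , 1][s$target[, , 2] == 1] == 1))

  expect_error(stack_25d(vol, lab, 6), "out of range")
  expect_error(stack_25d(vol, lab[, , 1:4], 1), "match")
})

test_that("augmentation preserves class counts, is seeded, and crops to size", {
  set.seed(94)
  vol <- array(runif(24 * 24 * 3), c(24, 24, 3))
  lab <- array(0L, c(24, 24, 3))
  lab[5:12, 7:18, 2] <- 1L
  lab[8:9, 10:12, 2] <- 2L
  s <- stack_25d(vol, lab, 2)

  # flips and quarter turns only (no crop): pixel counts preserved
  set.seed(95)
  a <- augment_sample(s, crop_size = 24)
  expect_identical(dim(a$image), c(24L, 24L, 3L))
  expect_equal(sum(a$target[, , 1]), sum(s$target[, , 1]))
  expect_equal(sum(a$target[, , 2]), sum(s$target[, , 2]))

  set.seed(96)
  b1 <- augment_sample(s, crop_size = 16)
  set.seed(96)
  b2 <- augment_sample(s, crop_size = 16)
  expect_identical(b1, b2)   # byte-identical under the same seed
  expect_identical(dim(b1$image), c(16L, 16L, 3L))
  expect_identical(dim(b1$target), c(16L, 16L, 2L))

  # image/mask geometric consistency: transform a mask rendered as image
  s2 <- s
  s2$image <- array(rep(s$target[, , 1], 3), dim(s$image))
  set.seed(97)
  a2 <- augment_sample(s2, crop_size = 24)
  expect_equal(a2$image[, , 1], a2$target[, , 1])

  # smaller-than-crop inputs are reflect-padded
  set.seed(98)
  small <- augment_sample(s, crop_size = 32)
  expect_identical(dim(small$image), c(32L, 32L, 3L))
})

test_that("training slice selection keeps liver slices plus a fraction of empties", {
  lab <- array(0L, c(4, 4, 10))
  lab[2, 2, c(3, 4, 5)] <- 1L
  set.seed(99)
  idx <- select_training_slices(lab, keep_empty_frac = 0)
  expect_identical(idx, c(3L, 4L, 5L))
  set.seed(99)
  idx2 <- select_training_slices(lab, keep_empty_frac = 1)
  expect_identical(idx2, 1:10)
})

test_that("volume-level splits are disjoint, seeded and near the 8:2 ratio", {
  sp <- split_volumes(100, 0.8, seed = 3)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(sp$val), 20L)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(sp, split_volumes(100, 0.8, seed = 3))
  expect_false(identical(sp, split_volumes(100, 0.8, seed = 4)))
})

test_that("NIfTI volumes round-trip through disk with spacing", {
  set.seed(100)
  v <- array(rnorm(12 * 12 * 6, 40, 80), c(12, 12, 6))
  attr(v, "spacing") <- c(1, 1, 5)
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, path)
  v2 <- read_nifti_volume(path)
  expect_equal(as.vector(v2), as.vector(v))
  expect_equal(attr(v2, "spacing")[1:3], c(1, 1, 5), ignore_attr = TRUE)
})

test_that("the full preprocessing chain yields unit-range images and binary targets", {
  p <- generate_phantom(phantom_spec(shape = c(6L, 32L, 32L)), seed = 5)
  vol <- preprocess_volume(p$volume)
  expect_true(all(vol >= 0 & vol <= 1))
  idx <- which(vapply(1:6, function(i) any(p$labels[, , i] > 0), logical(1)))[1]
  s <- stack_25d(vol, p$labels, idx)
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_true(all(s$target %in% c(0, 1)))
})
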