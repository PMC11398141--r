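# Convolutional building blocks: shape contracts, oracle equivalence,
# residual identity path, depthwise-separable parameter accounting.

test_that("conv1 unit preserves shape, applies ReLU, and matches a direct oracle", {
  set.seed(1)
  u <- conv1_unit(conv_spec(3, 8))
  x <- rand_fmap(16, 16, 2, 3, seed = 2)
  y <- nn_forward(u, x, training = TRUE)
  expect_identical(dim(y), c(16L, 16L, 2L, 8L))
  expect_true(all(y >= 0))

  ref <- naive_batchnorm(naive_conv2d(x, u$w), u$gamma, u$beta, u$eps)
  ref <- ref * (ref > 0)
  expect_lt(max(abs(y - ref)), 1e-5)

  expect_error(nn_forward(u, rand_fmap(8, 8, 1, 5)), "5 channels.*expects 3")
})

test_that("conv2 unit omits the activation and matches the conv+BN oracle", {
  set.seed(3)
  u <- conv2_unit(conv_spec(4, 6))
  x <- rand_fmap(10, 10, 2, 4, seed = 4)
  y <- nn_forward(u, x, training = TRUE)
  expect_identical(dim(y), c(10L, 10L, 2L, 6L))
  expect_true(any(y < 0))   # no ReLU clamping
  ref <- naive_batchnorm(naive_conv2d(x, u$w), u$gamma, u$beta, u$eps)
  expect_lt(max(abs(y - ref)), 1e-5)
})

test_that("residual blocks reduce to the skip path when the branch is zeroed", {
  set.seed(5)
  blk <- encoder_residual_block(3, 6)
  for (nm in c("c1", "c2", "c3")) {
    ch <- blk$children[[nm]]
    ch$w[] <- 0
    ch$gamma[] <- 0
    ch$beta[] <- 0
  }
  x <- rand_fmap(12, 12, 2, 3, seed = 6)
  y <- nn_forward(blk, x, training = TRUE)
  a <- nn_forward(blk$children$u1, x, training = TRUE)
  ref <- nn_forward(blk$children$final, a, training = TRUE)
  expect_lt(max(abs(y - ref)), 1e-10)

  # the skip path still carries gradient when the branch is dead
  gx <- nn_backward(blk, array(1, dim(y)))
  expect_true(all(is.finite(gx)))
  expect_gt(max(abs(gx)), 0)
})

test_that("decoder block uses ELU: outputs bounded below by -alpha, distinct from encoder", {
  set.seed(7)
  dec <- decoder_residual_block(3, 4)
  x <- rand_fmap(10, 10, 1, 3, seed = 8) - 3   # negative-heavy input
  y <- nn_forward(dec, x, training = TRUE)
  expect_true(any(y < 0))
  expect_true(all(y >= -1 - 1e-12))

  set.seed(7)
  enc <- encoder_residual_block(3, 4)   # identical weights by seed
  expect_equal(enc$children$u1$w, dec$children$u1$w)
  ye <- nn_forward(enc, x, training = TRUE)
  expect_gt(max(abs(y - ye)), 1e-3)
  expect_true(all(ye >= 0))
})

test_that("residual blocks match a full forward oracle composed of unit oracles", {
  set.seed(9)
  blk <- encoder_residual_block(2, 5)
  x <- rand_fmap(9, 9, 2, 2, seed = 10)
  y <- nn_forward(blk, x, training = TRUE)
  unit_ref <- function(u, z, act) {
    r <- naive_batchnorm(naive_conv2d(z, u$w), u$gamma, u$beta, u$eps)
    if (act) r * (r > 0) else r
  }
  ch <- blk$children
  a <- unit_ref(ch$u1, x, TRUE)
  b <- unit_ref(ch$c3, unit_ref(ch$c2, unit_ref(ch$c1, a, TRUE), TRUE), FALSE)
  ref <- unit_ref(ch$final, a + b, TRUE)
  expect_lt(max(abs(y - ref)), 1e-5)
})

test_that("depthwise-separable parameter counts follow the closed form", {
  m <- depthwise_separable_dilated_conv(
    conv_spec(32, 32, kernel = 3, dilation = 4, depthwise_separable = TRUE),
    bias = FALSE)
  expect_identical(n_parameters(m), 32 * 9 + 32 * 32)       # 1312
  expect_lt(n_parameters(m), 32 * 32 * 9)                   # standard conv: 9216

  m2 <- depthwise_separable_dilated_conv(
    conv_spec(8, 4, kernel = 3, dilation = 8, depthwise_separable = TRUE),
    bias = TRUE)
  expect_identical(n_parameters(m2), 8 * 9 + 8 + 8 * 4 + 4)

  expect_error(conv_spec(4, 4, kernel = 4), "odd")
  expect_error(depthwise_separable_dilated_conv(conv_spec(4, 4)),
               "depthwise_separable")
})

test_that("dilated depthwise-separable convolution matches the zero-inserted-kernel oracle", {
  set.seed(11)
  for (dil in c(1, 4, 8, 12)) {
    m <- depthwise_separable_dilated_conv(
      conv_spec(4, 3, kernel = 3, dilation = dil, depthwise_separable = TRUE))
    x <- rand_fmap(9, 9, 1, 4)
    y <- nn_forward(m, x)
    dw <- naive_dilated_via_zero_insertion(x, m$children$dw$w, m$children$dw$b,
                                           dilation = dil, groups = 4)
    ref <- naive_conv2d(dw, m$children$pw$w, m$children$pw$b, padding = 0)
    expect_lt(max(abs(y - ref)), 1e-5)
  }
})

test_that("all blocks preserve spatial dimensions for arbitrary sizes", {
  set.seed(12)
  sizes <- list(c(9, 11), c(16, 9), c(13, 13))
  for (sz in sizes) {
    x <- rand_fmap(sz[1], sz[2], 1, 3)
    for (make in list(function() encoder_residual_block(3, 4),
                      function() decoder_residual_block(3, 4),
                      function() depthwise_separable_dilated_conv(
                        conv_spec(3, 4, dilation = 4, depthwise_separable = TRUE)))) {
      y <- nn_forward(make(), x, training = TRUE)
      expect_identical(dim(y)[1:2], dim(x)[1:2])
    }
  }
})

test_that("block backward passes agree with numeric differentiation", {
  x <- rand_fmap(6, 6, 1, 2, seed = 13)
  ct <- rand_fmap(6, 6, 1, 3, seed = 14)
  make <- function() {
    set.seed(15)
    encoder_residual_block(2, 3)
  }
  m <- make()
  y <- nn_forward(m, x, training = TRUE)
  gx <- nn_backward(m, ct)
  gnum <- numeric_grad_input(make, x, ct)
  expect_lt(max(abs(gx - gnum)), 1e-6)
})

test_that("effective receptive field follows k + (k-1)(d-1)", {
  expect_identical(effective_receptive_field(3, 12), 25)
  expect_identical(effective_receptive_field(3, 4), 9)
  expect_identical(effective_receptive_field(7, 1), 7)
})
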