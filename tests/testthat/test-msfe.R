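# Multi-Scale Feature Enhancement bottleneck: branch shapes, dilated-branch
# oracles, the global-context reweighting, and liveness in the assembled net.

test_that("the pyramid concatenates five branches and fuses to out_channels", {
  set.seed(41)
  cfg <- msfe_config(16, branch_channels = 16, out_channels = 16)
  m <- msfe(cfg)
  x <- rand_fmap(30, 30, 2, 16, seed = 42)
  cat5 <- m$branches_fwd(x)
  expect_identical(dim(cat5), c(30L, 30L, 2L, 80L))   # 5 x branch_channels
  fused <- nn_forward(m$children$fuse, cat5, training = TRUE)
  expect_identical(dim(fused), c(30L, 30L, 2L, 16L))
  y <- nn_forward(m, x, training = TRUE)
  expect_identical(dim(y), dim(x))
})

test_that("a constant field leaves every branch spatially constant in the interior", {
  set.seed(43)
  m <- msfe(msfe_config(3, 4, 4))
  x <- array(2.5, c(30, 30, 1, 3))
  invisible(m$branches_fwd(x))
  for (nm in c("dil4", "dil8", "dil12")) {
    br <- nn_forward(m$children[[nm]], x)
    dil <- m$children[[nm]]$children$dw$dilation
    core <- br[(dil + 1):(30 - dil), (dil + 1):(30 - dil), 1, , drop = FALSE]
    expect_lt(max(abs(sweep(core, 4, core[1, 1, 1, ]))), 1e-10)
  }
})

test_that("each dilated branch matches the zero-inserted-kernel oracle", {
  set.seed(44)
  m <- msfe(msfe_config(4, 3, 3))
  x <- rand_fmap(13, 13, 1, 4, seed = 45)
  for (nm in c("dil4", "dil8", "dil12")) {
    br <- m$children[[nm]]
    y <- nn_forward(br, x)
    dw <- naive_dilated_via_zero_insertion(x, br$children$dw$w, br$children$dw$b,
                                           dilation = br$children$dw$dilation,
                                           groups = 4)
    ref <- naive_conv2d(dw, br$children$pw$w, br$children$pw$b, padding = 0)
    expect_lt(max(abs(y - ref)), 1e-5)
  }
})

test_that("global-context reweighting degenerates to 1.5x with a zero-weighted path", {
  m <- global_context_reweight(5)
  m$children$unit$w[] <- 0
  m$children$unit$beta[] <- 0
  x <- rand_fmap(6, 6, 2, 5, seed = 46)
  y <- nn_forward(m, x, training = TRUE)
  expect_equal(y, 1.5 * x, tolerance = 1e-12)
  expect_identical(dim(y), dim(x))
})

test_that("global-context reweighting matches an explicit pooled-attention oracle", {
  set.seed(47)
  m <- global_context_reweight(4)
  x <- rand_fmap(7, 7, 2, 4, seed = 48)
  y <- nn_forward(m, x, training = TRUE)

  p <- array(0, c(1, 1, 2, 4))
  for (n in 1:2) for (cc in 1:4) p[1, 1, n, cc] <- mean(x[, , n, cc])
  q <- naive_batchnorm(naive_conv2d(p, m$children$unit$w, padding = 0),
                       m$children$unit$gamma, m$children$unit$beta,
                       m$children$unit$eps)
  a <- sigmoid_ref(pmax(q, 0))
  ref <- x
  for (n in 1:2) for (cc in 1:4) {
    ref[, , n, cc] <- x[, , n, cc] * a[1, 1, n, cc] + x[, , n, cc]
  }
  expect_lt(max(abs(y - ref)), 1e-6)

  # bounded: |out| <= 2 |in| elementwise since a is in (0, 1)
  expect_true(all(abs(y) <= 2 * abs(x) + 1e-12))
})

test_that("the bottleneck preserves shape at full width and reaches all branches", {
  set.seed(49)
  m <- msfe(msfe_config(64, 128, 128))
  x <- rand_fmap(12, 12, 1, 64, seed = 50)
  suppressWarnings(y <- nn_forward(m, x, training = TRUE))
  expect_identical(dim(y), c(12L, 12L, 1L, 128L))

  nn_backward(m, array(1, dim(y)))
  for (nm in c("b1", "dil4", "dil8", "dil12", "pool_conv")) {
    mod <- m$children[[nm]]
    gw <- if (!is.null(mod$gw)) mod$gw else mod$children$dw$gw
    expect_gt(max(abs(gw)), 0)
  }
})

test_that("msfe backward agrees with numeric differentiation", {
  x <- rand_fmap(13, 13, 1, 3, seed = 51)
  ct <- rand_fmap(13, 13, 1, 4, seed = 52)
  make <- function() {
    set.seed(53)
    msfe(msfe_config(3, 4, 4))
  }
  m <- make()
  nn_forward(m, x, training = TRUE)
  gx <- nn_backward(m, ct)
  gnum <- numeric_grad_input(make, x, ct)
  expect_lt(max(abs(gx - gnum)), 1e-6)
})

test_that("the pre-fusion reweighting variant is available behind the config flag", {
  set.seed(54)
  m <- msfe(msfe_config(3, 4, 5, reweight_pre_fusion = TRUE))
  x <- rand_fmap(13, 13, 1, 3, seed = 55)
  y <- nn_forward(m, x, training = TRUE)
  expect_identical(dim(y), c(13L, 13L, 1L, 5L))
  expect_identical(m$children$reweight$channels, 20L)   # 5 branches x 4
})
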