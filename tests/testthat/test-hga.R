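# Hybrid Gated Attention: degeneracies, step-by-step oracles, gate endpoints,
# convex-combination properties.

test_that("channel attention with zero weights outputs 0.5 everywhere", {
  ca <- channel_attention(6, r = 2)
  ca$w1[] <- 0; ca$b1[] <- 0; ca$w2[] <- 0; ca$b2[] <- 0
  x <- array(3.7, c(5, 5, 2, 6))
  fc <- nn_forward(ca, x)
  expect_equal(as.vector(ca$last$map), rep(0.5, 12))
  expect_equal(fc, 0.5 * x)
})

test_that("channel attention matches the step-by-step oracle and is contractive", {
  set.seed(21)
  ca <- channel_attention(8, r = 2)
  x <- rand_fmap(6, 6, 2, 8, seed = 22)
  fc <- nn_forward(ca, x)

  p <- matrix(0, 2, 8)
  for (n in 1:2) for (cc in 1:8) p[n, cc] <- mean(x[, , n, cc])
  z <- p %*% ca$w1 + matrix(ca$b1, 2, ncol(ca$w1), byrow = TRUE)
  s <- pmax(z, 0) %*% ca$w2 + matrix(ca$b2, 2, 8, byrow = TRUE)
  wc <- sigmoid_ref(s)
  ref <- x
  for (n in 1:2) for (cc in 1:8) ref[, , n, cc] <- x[, , n, cc] * wc[n, cc]
  expect_lt(max(abs(fc - ref)), 1e-6)

  expect_true(all(ca$last$map > 0 & ca$last$map < 1))
  expect_true(all(abs(fc) <= abs(x) + 1e-12))
  expect_identical(ca$bottleneck, 4L)
  expect_identical(channel_attention(8, r = 16)$bottleneck, 1L)  # capped
})

test_that("spatial attention matches the naive mean/max + 7x7 oracle", {
  set.seed(23)
  sa <- spatial_attention()
  x <- rand_fmap(9, 9, 1, 4, seed = 24)
  fs <- nn_forward(sa, x)

  mu <- apply(x, c(1, 2, 3), mean)
  mx <- apply(x, c(1, 2, 3), max)
  pooled <- array(c(mu, mx), c(9, 9, 1, 2))
  ws <- sigmoid_ref(naive_conv2d(pooled, sa$children$conv7$w,
                                 sa$children$conv7$b, padding = 3))
  ref <- x
  for (cc in 1:4) ref[, , 1, cc] <- x[, , 1, cc] * ws[, , 1, 1]
  expect_lt(max(abs(fs - ref)), 1e-6)
  expect_true(all(sa$last$map > 0 & sa$last$map < 1))
  expect_true(all(abs(fs) <= abs(x) + 1e-12))
})

test_that("spatial attention is well defined when all channels are identical", {
  set.seed(25)
  sa <- spatial_attention()
  one <- rand_fmap(8, 8, 2, 1, seed = 26)
  x <- array(rep(one, 3), c(8, 8, 2, 3))
  fs <- nn_forward(sa, x)
  expect_identical(dim(sa$last$map), c(8L, 8L, 2L, 1L))
  expect_true(all(is.finite(fs)))
})

test_that("the gate matches its step-by-step oracle and degenerates to 0.5", {
  set.seed(27)
  g <- attention_gate(4)
  # zero-initialised final conv: untrained gate is exactly 0.5
  fc <- rand_fmap(7, 7, 2, 4, seed = 28)
  fs <- rand_fmap(7, 7, 2, 4, seed = 29)
  out <- g$fwd2(fc, fs)
  expect_identical(dim(out), c(7L, 7L, 2L, 1L))
  expect_true(all(out == 0.5))

  # randomise the gate weights and compare against the explicit composition
  set.seed(30)
  g$children$c2$w[] <- rnorm(length(g$children$c2$w))
  g$children$c2$b[] <- rnorm(length(g$children$c2$b))
  out <- g$fwd2(fc, fs)
  cat2 <- array(c(fc, fs), c(7, 7, 2, 8))
  h <- naive_conv2d(cat2, g$children$c1$w, g$children$c1$b, padding = 0)
  ref <- sigmoid_ref(naive_conv2d(pmax(h, 0), g$children$c2$w,
                                  g$children$c2$b, padding = 0))
  expect_lt(max(abs(out - ref)), 1e-6)
  expect_true(all(out > 0 & out < 1))

  expect_error(g$fwd2(fc, rand_fmap(7, 7, 2, 3)), "identical shapes")
})

test_that("gate bias surgery drives the fusion to its FC / FS endpoints", {
  set.seed(31)
  m <- hga(5, r = 2)
  x <- rand_fmap(8, 8, 2, 5, seed = 32)

  m$children$gate$children$c2$b[] <- -1000   # sigmoid underflows to exactly 0
  y0 <- nn_forward(m, x)
  expect_identical(y0, m$last$FC)

  m$children$gate$children$c2$b[] <- 1000    # sigmoid saturates to exactly 1
  y1 <- nn_forward(m, x)
  expect_identical(y1, m$last$FS)
})

test_that("the fused output is an elementwise convex combination of FC and FS", {
  set.seed(33)
  m <- hga(6, r = 2)
  # give the gate non-trivial weights
  m$children$gate$children$c2$w[] <- rnorm(length(m$children$gate$children$c2$w))
  x <- rand_fmap(9, 9, 2, 6, seed = 34)
  y <- nn_forward(m, x)
  C <- 6
  lo <- pmin(m$last$FC, m$last$FS)
  hi <- pmax(m$last$FC, m$last$FS)
  expect_true(all(y >= lo - 1e-12 & y <= hi + 1e-12))
  expect_true(all(m$last$gate > 0 & m$last$gate < 1))

  # FC = FS makes the blend the identity for any gate value
  g <- rand_fmap(9, 9, 2, 1, seed = 35)
  g <- sigmoid_ref(g)
  blended <- rheunet:::cpp_blend_forward(m$last$FC, m$last$FC, g)
  expect_identical(blended, m$last$FC)
})

test_that("hga is differentiable end to end with finite gradients", {
  set.seed(36)
  m <- hga(4, r = 2)
  x <- rand_fmap(8, 8, 2, 4, seed = 37)
  y <- nn_forward(m, x, training = TRUE)
  gx <- nn_backward(m, array(1, dim(y)))
  expect_true(all(is.finite(gx)))
  for (p in nn_parameters(m)) {
    g <- p$env[[paste0("g", p$name)]]
    expect_true(!is.null(g) && all(is.finite(g)))
  }
})

test_that("hga backward agrees with numeric differentiation", {
  x <- rand_fmap(6, 6, 1, 4, seed = 38)
  ct <- rand_fmap(6, 6, 1, 4, seed = 39)
  make <- function() {
    set.seed(40)
    m <- hga(4, r = 2)
    m$children$gate$children$c2$w[] <- 0.3
    m$children$gate$children$c2$b[] <- -0.1
    m
  }
  m <- make()
  nn_forward(m, x, training = TRUE)
  gx <- nn_backward(m, ct)
  gnum <- numeric_grad_input(make, x, ct)
  expect_lt(max(abs(gx - gnum)), 1e-6)
})
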