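# Independent reference implementations used as oracles. These are written
# as plain, direct R loops over the mathematical definitions and share no
# code with the package's computational path.

# feature maps are (H, W, N, C) arrays
rand_fmap <- function(h, w, n, c, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * n * c, sd = sd), c(h, w, n, c))
}

# direct sliding-window convolution, stride 1, zero padding, optional
# dilation and channel groups; weights (k, k, Cin/groups, Cout)
naive_conv2d <- function(x, w, bias = NULL, dilation = 1, padding = NULL,
                         groups = 1) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(w)[1]
  Cout <- dim(w)[4]
  Cg <- Cin / groups
  CoG <- Cout / groups
  if (is.null(padding)) padding <- dilation * (k - 1) / 2
  y <- array(0, c(H, W, N, Cout))
  for (n in seq_len(N)) for (co in seq_len(Cout)) {
    g <- ceiling(co / CoG)
    acc <- matrix(if (is.null(bias)) 0 else bias[co], H, W)
    for (ci in seq_len(Cg)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      wv <- w[ki, kj, ci, co]
      if (wv == 0) next
      for (h in seq_len(H)) for (ww in seq_len(W)) {
        hh <- h + (ki - 1) * dilation - padding
        wc <- ww + (kj - 1) * dilation - padding
        if (hh >= 1 && hh <= H && wc >= 1 && wc <= W) {
          acc[h, ww] <- acc[h, ww] + wv * x[hh, wc, n, (g - 1) * Cg + ci]
        }
      }
    }
    y[, , n, co] <- acc
  }
  y
}

# dilated convolution realised explicitly as a dense kernel with inserted
# zeros (the zero-inserted-kernel oracle), then plain sliding window
naive_dilated_via_zero_insertion <- function(x, w, bias = NULL, dilation = 1,
                                             groups = 1) {
  k <- dim(w)[1]
  ke <- k + (k - 1) * (dilation - 1)
  we <- array(0, c(ke, ke, dim(w)[3], dim(w)[4]))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    we[1 + (ki - 1) * dilation, 1 + (kj - 1) * dilation, , ] <- w[ki, kj, , ]
  }
  naive_conv2d(x, we, bias, dilation = 1, padding = (ke - 1) / 2,
               groups = groups)
}

# batch normalisation with batch statistics (training mode, biased variance)
naive_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  R <- prod(d[1:3])
  m <- matrix(x, nrow = R)
  mu <- colMeans(m)
  va <- colMeans((m - rep(mu, each = R))^2)
  y <- (m - rep(mu, each = R)) / rep(sqrt(va + eps), each = R) *
    rep(gamma, each = R) + rep(beta, each = R)
  array(y, d)
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# numeric input gradient of a module via central differences, rebuilding the
# module fresh for every evaluation so caches cannot leak state
numeric_grad_input <- function(make_module, x, cotangent, eps = 1e-5,
                               training = TRUE) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (sum(nn_forward(make_module(), xp, training) * cotangent) -
               sum(nn_forward(make_module(), xm, training) * cotangent)) / (2 * eps)
  }
  g
}

# small phantom-derived training batch: images (S, S, B, 3), targets
# (S, S, B, 2); slices are chosen to contain liver (and tumor when available)
phantom_batch <- function(n = 4, size = 96, seed = 7) {
  spec <- phantom_spec(shape = c(12L, size, size), n_tumors = c(1L, 2L))
  x <- array(0, c(size, size, n, 3))
  y <- array(0, c(size, size, n, 2))
  for (b in seq_len(n)) {
    p <- generate_phantom(spec, seed = seed + b)
    vol <- preprocess_volume(p$volume)
    area <- vapply(seq_len(dim(p$labels)[3]),
                   function(i) sum(p$labels[, , i] == 2L), numeric(1))
    s <- stack_25d(vol, p$labels, which.max(area))
    x[, , b, ] <- s$image
    y[, , b, ] <- s$target
  }
  list(x = x, y = y)
}
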