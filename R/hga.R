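# Hybrid Gated Attention: parallel channel and spatial attention over the
# same encoder feature map, fused per pixel by a learned gate g in (0,1):
#
#   FC = F * sigmoid(W2 relu(W1 avgpool(F)))          channel attention
#   FS = F * sigmoid(conv7x7(cat(mean_c F, max_c F))) spatial attention
#   g  = sigmoid(conv1x1(relu(conv1x1(cat(FC, FS))))) gate (single channel)
#   out = (1 - g) * FC + g * FS
#
# Each block below keeps the attention maps from its last forward pass in
# `$last` for inspection and testing.

#' Channel attention (squeeze-and-excitation style)
#'
#' Global average pooling squeezes the feature map to one value per channel;
#' a two-layer bottleneck network (width `max(1, floor(C / r))`, ReLU inside,
#' sigmoid output) produces per-channel weights in (0, 1) that rescale the
#' input. The two dense layers are the 1x1-convolution reading of the usual
#' fully connected pair, applied to the pooled vector.
#'
#' @param channels Number of input channels C.
#' @param r Reduction ratio of the bottleneck (default 16, capped so the
#'   bottleneck keeps at least one unit).
#' @param use_max Also pool with a global max and pass it through the shared
#'   bottleneck, summing the two paths before the sigmoid (CBAM-style
#'   variant; default off, the plain average-pool form is canonical here).
#' @return A module. After `nn_forward()`, `$last$map` holds the channel
#'   attention map as a `(1, 1, N, C)` array.
#' @export
channel_attention <- function(channels, r = 16L, use_max = FALSE) {
  C <- as.integer(channels)
  if (C < 1L) stop("channels must be >= 1")
  r <- max(1L, as.integer(r))
  cb <- max(1L, C %/% r)
  self <- new_module("channel_attention")
  self$channels <- C
  self$r <- r
  self$bottleneck <- cb
  self$use_max <- isTRUE(use_max)
  self$w1 <- matrix(stats::rnorm(C * cb, sd = sqrt(2 / C)), C, cb)
  self$b1 <- numeric(cb)
  self$w2 <- matrix(stats::rnorm(cb * C, sd = sqrt(2 / cb)), cb, C)
  self$b2 <- numeric(C)
  self$param_names <- c("w1", "b1", "w2", "b2")
  self$decay_names <- c("w1", "w2")

  mlp_fwd <- function(p) {
    z <- p %*% self$w1 + matrix(self$b1, nrow(p), self$bottleneck, byrow = TRUE)
    zr <- z * (z > 0)
    list(z = z, zr = zr,
         s = zr %*% self$w2 + matrix(self$b2, nrow(p), self$channels, byrow = TRUE))
  }

  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    HW <- d[1L] * d[2L]; N <- d[3L]; C <- d[4L]
    if (C != self$channels) {
      stop(sprintf("input has %d channels but this attention expects %d", C, self$channels))
    }
    self$x <- x
    p <- matrix(sum_hw(x), N, C) / HW
    av <- mlp_fwd(p)
    s <- av$s
    if (self$use_max) {
      m <- matrix(x, nrow = HW)                   # columns indexed by (n, c)
      mx <- m[1L, ]; amax <- rep(1L, ncol(m))
      for (i in seq_len(HW)[-1L]) {
        sel <- m[i, ] > mx
        mx[sel] <- m[i, sel]; amax[sel] <- i
      }
      pm <- matrix(mx, N, C)
      mxp <- mlp_fwd(pm)
      s <- s + mxp$s
      self$mx_cache <- list(pm = pm, z = mxp$z, zr = mxp$zr, amax = amax)
    }
    wc <- 1 / (1 + exp(-s))
    self$p <- p; self$z <- av$z; self$zr <- av$zr; self$wc <- wc
    wca <- array(wc, c(1L, 1L, N, C))
    self$last <- list(map = wca)
    cpp_scale_nc_forward(x, wca, 0)
  }

  self$bwd <- function(gy) {
    x <- self$x
    d <- dim(x)
    HW <- d[1L] * d[2L]; N <- d[3L]; C <- d[4L]
    wc <- self$wc
    sc <- cpp_scale_nc_backward(gy, x, self$last$map, 0)
    gx <- sc$gx
    gwc <- matrix(sc$gv, N, C)
    gs <- gwc * wc * (1 - wc)
    bwd_mlp <- function(gs, p, z, zr) {
      gzr <- gs %*% t(self$w2)
      gz <- gzr * (z > 0)
      list(gw1 = t(p) %*% gz, gb1 = colSums(gz),
           gw2 = t(zr) %*% gs, gb2 = colSums(gs),
           gp = gz %*% t(self$w1))
    }
    av <- bwd_mlp(gs, self$p, self$z, self$zr)
    self$gw1 <- av$gw1; self$gb1 <- av$gb1
    self$gw2 <- av$gw2; self$gb2 <- av$gb2
    gx <- gx + rep(as.vector(av$gp), each = HW) / HW
    if (self$use_max) {
      mc <- self$mx_cache
      mxp <- bwd_mlp(gs, mc$pm, mc$z, mc$zr)
      self$gw1 <- self$gw1 + mxp$gw1; self$gb1 <- self$gb1 + mxp$gb1
      self$gw2 <- self$gw2 + mxp$gw2; self$gb2 <- self$gb2 + mxp$gb2
      idx <- (seq_len(N * C) - 1L) * HW + mc$amax
      gx[idx] <- gx[idx] + as.vector(mxp$gp)
    }
    gx
  }
  self
}

#' Spatial attention
#'
#' Channel-wise mean and max maps are concatenated to a 2-channel image,
#' convolved with a 7x7 kernel (padding 3), and squashed with a sigmoid into
#' a single-channel spatial weight map that rescales every channel.
#'
#' @return A module. `$last$map` holds the `(H, W, N, 1)` spatial map.
#' @export
spatial_attention <- function() {
  self <- new_module("spatial_attention")
  self$children <- list(conv7 = layer_conv2d(2L, 1L, kernel = 7L, padding = 3L,
                                             bias = TRUE, small = TRUE))
  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    HWN <- prod(d[1:3]); C <- d[4L]
    self$x <- x
    m <- matrix(x, ncol = C)
    mu <- rowMeans(m)
    mx <- m[, 1L]; amax <- rep(1L, HWN)
    if (C > 1L) {
      for (cc in 2:C) {
        sel <- m[, cc] > mx
        mx[sel] <- m[sel, cc]; amax[sel] <- cc
      }
    }
    self$amax <- amax
    pooled <- array(c(mu, mx), c(d[1L], d[2L], d[3L], 2L))
    s <- self$children$conv7$fwd(pooled, training)
    ws <- cpp_sigmoid_forward(s)
    self$ws <- ws
    self$last <- list(map = ws)
    cpp_scale_hwn_forward(x, ws)
  }
  self$bwd <- function(gy) {
    x <- self$x
    d <- dim(x)
    HWN <- prod(d[1:3]); C <- d[4L]
    ws <- self$ws
    sc <- cpp_scale_hwn_backward(gy, x, ws)
    gx <- sc$gx
    gs <- sc$gs * ws * (1 - ws)
    gpool <- self$children$conv7$bwd(gs)
    n1 <- HWN
    gmu <- as.vector(gpool)[seq_len(n1)]
    gmx <- as.vector(gpool)[n1 + seq_len(n1)]
    gx <- gx + rep(gmu / C, times = C)
    idx <- (self$amax - 1L) * HWN + seq_len(HWN)
    gx[idx] <- gx[idx] + gmx
    gx
  }
  self
}

#' Attention gate
#'
#' Concatenates the channel- and spatially-weighted feature maps (2C
#' channels), halves the width with a 1x1 convolution + ReLU, and projects to
#' a single channel through a second 1x1 convolution + sigmoid. The final
#' convolution is zero-initialised so an untrained gate outputs exactly 0.5,
#' an unbiased average of the two attention streams.
#'
#' @param channels Channel count C of each input stream.
#' @param width Width of the intermediate layer; default C ("half of 2C").
#' @return A module with `fwd2(FC, FS)` / `bwd2(g_grad)` entry points.
#' @export
attention_gate <- function(channels, width = NULL) {
  C <- as.integer(channels)
  if (is.null(width)) width <- C
  self <- new_module("attention_gate")
  self$channels <- C
  self$children <- list(
    c1 = layer_conv2d(2L * C, as.integer(width), kernel = 1L, bias = TRUE),
    c2 = layer_conv2d(as.integer(width), 1L, kernel = 1L, bias = TRUE,
                      init_zero = TRUE)
  )
  self$fwd2 <- function(fc, fs, training = FALSE) {
    dc <- check_fmap(fc, "FC"); ds <- check_fmap(fs, "FS")
    if (!identical(dc, ds)) {
      stop(sprintf("FC (%s) and FS (%s) must have identical shapes",
                   paste(dc, collapse = "x"), paste(ds, collapse = "x")))
    }
    cat2 <- cpp_cat_channels(fc, fs)
    h <- cpp_relu_forward(self$children$c1$fwd(cat2, training))
    self$h <- h
    s <- self$children$c2$fwd(h, training)
    g <- cpp_sigmoid_forward(s)
    self$g <- g
    self$dims <- dc
    g
  }
  self$bwd2 <- function(gg) {
    g <- self$g
    gs <- gg * g * (1 - g)
    gh <- cpp_relu_backward(self$h, self$children$c2$bwd(gs))
    gcat <- self$children$c1$bwd(gh)
    parts <- cpp_split_channels(gcat, self$dims[4L])
    list(gfc = parts$a, gfs = parts$b)
  }
  # plain fwd so the gate can also be probed standalone on a duplicated input
  self$fwd <- function(x, training = FALSE) self$fwd2(x, x, training)
  self$bwd <- function(gg) {
    r <- self$bwd2(gg)
    r$gfc + r$gfs
  }
  self
}

#' Hybrid Gated Attention module
#'
#' Runs channel and spatial attention in parallel on the same feature map and
#' blends the two results with a learned per-pixel convex combination:
#' `out = (1 - g) * FC + g * FS`. Applied to each encoder feature map before
#' it is concatenated into the decoder.
#'
#' @param channels Number of channels of the gated feature map.
#' @param r Channel-attention reduction ratio (default 16).
#' @param use_max_channel Enable the average+max channel-pooling variant.
#' @param gate_width Intermediate width of the gate (default `channels`).
#' @return A module. `$last` keeps `FC`, `FS` and the gate map of the most
#'   recent forward pass.
#' @export
hga <- function(channels, r = 16L, use_max_channel = FALSE, gate_width = NULL) {
  C <- as.integer(channels)
  self <- new_module("hga")
  self$channels <- C
  self$children <- list(
    ca = channel_attention(C, r = r, use_max = use_max_channel),
    sa = spatial_attention(),
    gate = attention_gate(C, width = gate_width)
  )
  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    fc <- ch$ca$fwd(x, training)
    fs <- ch$sa$fwd(x, training)
    g <- ch$gate$fwd2(fc, fs, training)
    self$fc <- fc; self$fs <- fs; self$g <- g
    self$last <- list(FC = fc, FS = fs, gate = g,
                      channel_map = ch$ca$last$map,
                      spatial_map = ch$sa$last$map)
    cpp_blend_forward(fc, fs, g)
  }
  self$bwd <- function(gy) {
    ch <- self$children
    bl <- cpp_blend_backward(gy, self$fc, self$fs, self$g)
    gl <- ch$gate$bwd2(bl$gg)
    ch$ca$bwd(bl$gfc + gl$gfc) + ch$sa$bwd(bl$gfs + gl$gfs)
  }
  self
}
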