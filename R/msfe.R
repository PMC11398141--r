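# Multi-Scale Feature Enhancement bottleneck: an atrous-spatial-pyramid block
# (1x1 conv; depthwise-separable 3x3 dilated convs at rates 4, 8, 12; a
# global-average-pooling branch) fused by a 1x1 convolution, followed by a
# global-context channel reweighting with an additive skip, and a final 1x1
# projection.

#' MSFE configuration
#'
#' @param in_channels Channels entering the bottleneck.
#' @param branch_channels Output width of each of the five pyramid branches.
#' @param out_channels Width after fusion (and of the module output).
#' @param dilation_rates Dilation rates of the three dilated branches.
#' @param reweight_pre_fusion If `TRUE` the global-context reweighting is
#'   applied to the 5-branch concatenation before fusion instead of to the
#'   fused map (default `FALSE`: reweight the fused representation).
#' @return An object of class `msfe_config`.
#' @export
msfe_config <- function(in_channels, branch_channels = in_channels,
                        out_channels = branch_channels,
                        dilation_rates = c(4L, 8L, 12L),
                        reweight_pre_fusion = FALSE) {
  stopifnot(in_channels >= 1, branch_channels >= 1, out_channels >= 1,
            length(dilation_rates) >= 1, all(dilation_rates >= 1))
  structure(list(in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rates = as.integer(dilation_rates),
                 reweight_pre_fusion = isTRUE(reweight_pre_fusion)),
            class = "msfe_config")
}

#' Global-context channel reweighting with skip connection
#'
#' Computes a per-channel attention map `a = sigmoid(relu(bn(conv1x1(gap(x)))))`
#' from globally pooled features and returns `x * a + x`: the reweighted map
#' plus an additive skip. With a zero-weighted attention path `a = 0.5`
#' everywhere, so the module starts as a benign 1.5x rescaling.
#'
#' @param channels Channel count of the reweighted map.
#' @return A network module.
#' @export
global_context_reweight <- function(channels) {
  C <- as.integer(channels)
  self <- new_module("global_context_reweight")
  self$channels <- C
  self$children <- list(
    gap = layer_gap(),
    unit = layer_conv_unit(C, C, kernel = 1L, activation = "relu"),
    sig = layer_sigmoid()
  )
  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    d <- check_fmap(x)
    q <- ch$unit$fwd(ch$gap$fwd(x, training), training)
    a <- ch$sig$fwd(q, training)              # (1, 1, N, C)
    self$x <- x
    self$a <- a
    self$last <- list(map = a)
    cpp_scale_nc_forward(x, a, 1)
  }
  self$bwd <- function(gy) {
    ch <- self$children
    sc <- cpp_scale_nc_backward(gy, self$x, self$a, 1)
    sc$gx + ch$gap$bwd(ch$unit$bwd(ch$sig$bwd(sc$gv)))
  }
  self
}

#' Multi-Scale Feature Enhancement module
#'
#' Five parallel branches read the bottleneck feature map: a 1x1 convolution,
#' three 3x3 depthwise-separable dilated convolutions (rates 4, 8, 12), and a
#' global-average-pooling branch (pooled to 1x1, 1x1-convolved, broadcast back
#' to H x W). Branch outputs are concatenated, fused by a 1x1 convolution +
#' batch norm + ReLU, passed through [global_context_reweight()], and
#' projected by a final 1x1 convolution.
#'
#' @param cfg An [msfe_config()].
#' @return A network module. Inputs smaller than 13 pixels trigger a warning
#'   (the rate-12 branch then sees mostly padding) but still compute.
#' @export
msfe <- function(cfg) {
  stopifnot(inherits(cfg, "msfe_config"))
  self <- new_module("msfe")
  self$cfg <- cfg
  Cin <- cfg$in_channels; Cb <- cfg$branch_channels; Cout <- cfg$out_channels
  rates <- cfg$dilation_rates
  nb <- 2L + length(rates)
  dil <- lapply(rates, function(r) {
    depthwise_separable_dilated_conv(conv_spec(Cin, Cb, kernel = 3L,
                                               dilation = r,
                                               depthwise_separable = TRUE))
  })
  names(dil) <- paste0("dil", rates)
  rw_channels <- if (cfg$reweight_pre_fusion) nb * Cb else Cout
  self$children <- c(
    list(b1 = layer_conv2d(Cin, Cb, kernel = 1L, bias = TRUE)),
    dil,
    list(
      pool_conv = layer_conv2d(Cin, Cb, kernel = 1L, bias = TRUE),
      gap = layer_gap(),
      fuse = layer_conv_unit(nb * Cb, Cout, kernel = 1L, activation = "relu"),
      reweight = global_context_reweight(rw_channels),
      final = layer_conv2d(Cout, Cout, kernel = 1L, bias = TRUE)
    )
  )
  self$dil_names <- names(dil)

  self$branches_fwd <- function(x, training = FALSE) {
    ch <- self$children
    d <- check_fmap(x)
    if ((d[1L] < 13L || d[2L] < 13L) && !isTRUE(self$warned_small)) {
      self$warned_small <- TRUE
      warning("input smaller than 13 pixels: the largest dilation rate sees mostly padding")
    }
    outs <- list(ch$b1$fwd(x, training))
    for (nm in self$dil_names) outs <- c(outs, list(ch[[nm]]$fwd(x, training)))
    pooled <- ch$pool_conv$fwd(ch$gap$fwd(x, training), training)
    self$pool_hw <- d[1:2]
    outs <- c(outs, list(rep_nc(pooled, d[1L], d[2L])))   # nearest upsample
    array(unlist(outs, use.names = FALSE),
          c(d[1L], d[2L], d[3L], length(outs) * dim(outs[[1L]])[4L]))
  }
  self$branches_bwd <- function(gcat) {
    ch <- self$children
    d <- dim(gcat)
    Cb <- self$cfg$branch_channels
    n1 <- prod(d[1:3]) * Cb
    v <- as.vector(gcat)
    sub <- function(i) array(v[(i - 1L) * n1 + seq_len(n1)],
                             c(d[1L], d[2L], d[3L], Cb))
    gx <- ch$b1$bwd(sub(1L))
    for (i in seq_along(self$dil_names)) {
      gx <- gx + ch[[self$dil_names[i]]]$bwd(sub(i + 1L))
    }
    gpool <- sum_hw(sub(2L + length(self$dil_names)))    # broadcast transpose
    gx + ch$gap$bwd(ch$pool_conv$bwd(gpool))
  }

  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    cat5 <- self$branches_fwd(x, training)
    if (self$cfg$reweight_pre_fusion) {
      fused <- ch$fuse$fwd(ch$reweight$fwd(cat5, training), training)
    } else {
      fused <- ch$reweight$fwd(ch$fuse$fwd(cat5, training), training)
    }
    ch$final$fwd(fused, training)
  }
  self$bwd <- function(gy) {
    ch <- self$children
    g <- ch$final$bwd(gy)
    if (self$cfg$reweight_pre_fusion) {
      g <- ch$reweight$bwd(ch$fuse$bwd(g))
    } else {
      g <- ch$fuse$bwd(ch$reweight$bwd(g))
    }
    self$branches_bwd(g)
  }
  self
}
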