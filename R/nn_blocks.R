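# Convolutional building blocks: conv1/conv2 units, the residual encoder and
# decoder modules, and the depthwise-separable dilated convolution primitive.

#' Convolution specification
#'
#' Bundles the hyper-parameters of a single 2-d convolution. Padding defaults
#' to `dilation * (kernel - 1) / 2`, which preserves spatial dimensions for
#' odd kernels at stride 1.
#'
#' @param in_channels,out_channels Channel counts (positive integers).
#' @param kernel Odd kernel size (default 3).
#' @param dilation Dilation rate (>= 1).
#' @param depthwise_separable If `TRUE`, the convolution is factored into a
#'   per-channel spatial convolution followed by a 1x1 pointwise mixing.
#' @param padding Zero-padding; leave `NULL` for the shape-preserving default.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel = 3L, dilation = 1L,
                      depthwise_separable = FALSE, padding = NULL) {
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  kernel <- as.integer(kernel)
  dilation <- as.integer(dilation)
  if (in_channels < 1L || out_channels < 1L) {
    stop("in_channels and out_channels must be positive")
  }
  if (kernel < 1L || kernel %% 2L == 0L) stop("kernel must be a positive odd integer")
  if (dilation < 1L) stop("dilation must be >= 1")
  if (is.null(padding)) padding <- dilation * (kernel - 1L) %/% 2L
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 kernel = kernel, dilation = dilation,
                 depthwise_separable = isTRUE(depthwise_separable),
                 padding = as.integer(padding)),
            class = "conv_spec")
}

#' conv1 unit: convolution + batch normalisation + activation
#'
#' The basic unit of the residual modules: a 3x3 convolution (no bias, since
#' the normalisation shift makes it redundant), batch normalisation, and a
#' ReLU (encoder) or ELU (decoder) activation.
#'
#' @param spec A [conv_spec()].
#' @param activation `"relu"` or `"elu"`.
#' @return A network module; run it with [nn_forward()].
#' @export
conv1_unit <- function(spec, activation = c("relu", "elu")) {
  activation <- match.arg(activation)
  stopifnot(inherits(spec, "conv_spec"))
  m <- layer_conv_unit(spec$in_channels, spec$out_channels, spec$kernel,
                       spec$dilation, padding = spec$padding,
                       activation = activation)
  m$type <- "conv1_unit"
  class(m) <- c("conv1_unit", class(m))
  m
}

#' conv2 unit: convolution + batch normalisation, no activation
#'
#' Same as [conv1_unit()] but without the activation; this is the unit whose
#' output enters the residual addition.
#'
#' @inheritParams conv1_unit
#' @return A network module.
#' @export
conv2_unit <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  m <- layer_conv_unit(spec$in_channels, spec$out_channels, spec$kernel,
                       spec$dilation, padding = spec$padding,
                       activation = "none")
  m$type <- "conv2_unit"
  class(m) <- c("conv2_unit", class(m))
  m
}

residual_block <- function(in_ch, out_ch, activation) {
  in_ch <- as.integer(in_ch); out_ch <- as.integer(out_ch)
  if (in_ch < 1L || out_ch < 1L) {
    stop("residual block configuration error: channel counts must be positive")
  }
  self <- new_module("residual_block")
  self$activation <- activation
  # u1 changes width in -> out; every later unit works at out -> out so the
  # residual addition a + F(a) is well typed without a projection shortcut.
  self$children <- list(
    u1 = conv1_unit(conv_spec(in_ch, out_ch), activation),
    c1 = conv1_unit(conv_spec(out_ch, out_ch), activation),
    c2 = conv1_unit(conv_spec(out_ch, out_ch), activation),
    c3 = conv2_unit(conv_spec(out_ch, out_ch)),
    final = conv1_unit(conv_spec(out_ch, out_ch), activation)
  )
  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    a <- ch$u1$fwd(x, training)
    b <- ch$c3$fwd(ch$c2$fwd(ch$c1$fwd(a, training), training), training)
    ch$final$fwd(a + b, training)
  }
  self$bwd <- function(gy) {
    ch <- self$children
    gr <- ch$final$bwd(gy)
    ga <- gr + ch$c1$bwd(ch$c2$bwd(ch$c3$bwd(gr)))
    ch$u1$bwd(ga)
  }
  self
}

#' Residual encoder / decoder blocks
#'
#' The residual module that replaces U-Net's double convolution. The input is
#' first brought to `out_ch` channels by a conv1 unit (output `a`), a
#' three-segment sequence (conv1, conv1, conv2) computes the residual branch
#' `F(a)`, the skip addition forms `a + F(a)`, and a last conv1 unit produces
#' the block output. The encoder block activates with ReLU, the decoder block
#' with ELU (alpha = 1) to keep gradients alive for negative responses during
#' reconstruction.
#'
#' @param in_ch,out_ch Input and output channel counts.
#' @return A network module.
#' @export
encoder_residual_block <- function(in_ch, out_ch) {
  m <- residual_block(in_ch, out_ch, "relu")
  m$type <- "encoder_residual_block"
  class(m) <- c("encoder_residual_block", class(m))
  m
}

#' @rdname encoder_residual_block
#' @export
decoder_residual_block <- function(in_ch, out_ch) {
  m <- residual_block(in_ch, out_ch, "elu")
  m$type <- "decoder_residual_block"
  class(m) <- c("decoder_residual_block", class(m))
  m
}

# plain double conv block (baseline U-Net stage)
double_conv_block <- function(in_ch, out_ch, activation = "relu") {
  m <- nn_sequential(
    u1 = conv1_unit(conv_spec(in_ch, out_ch), activation),
    u2 = conv1_unit(conv_spec(out_ch, out_ch), activation)
  )
  m$type <- "double_conv_block"
  class(m) <- c("double_conv_block", class(m))
  m
}

#' Depthwise-separable dilated convolution
#'
#' A dilated spatial convolution applied independently to each input channel
#' (depthwise), followed by a 1x1 pointwise convolution that mixes channels.
#' Parameter count is `Cin * k^2 + Cin * Cout` (plus biases when enabled),
#' versus `Cin * Cout * k^2` for a standard convolution.
#'
#' @param spec A [conv_spec()] with `depthwise_separable = TRUE`.
#' @param bias Add bias terms to both stages (default `TRUE`).
#' @return A network module.
#' @export
depthwise_separable_dilated_conv <- function(spec, bias = TRUE) {
  stopifnot(inherits(spec, "conv_spec"))
  if (!spec$depthwise_separable) {
    stop("spec must have depthwise_separable = TRUE")
  }
  m <- nn_sequential(
    dw = layer_conv2d(spec$in_channels, spec$in_channels, spec$kernel,
                      spec$dilation, groups = spec$in_channels,
                      padding = spec$padding, bias = bias),
    pw = layer_conv2d(spec$in_channels, spec$out_channels, kernel = 1L,
                      bias = bias)
  )
  m$type <- "depthwise_separable_dilated_conv"
  class(m) <- c("depthwise_separable_dilated_conv", class(m))
  m
}

#' Effective receptive field of a dilated kernel
#'
#' @param kernel Kernel size.
#' @param dilation Dilation rate.
#' @return `kernel + (kernel - 1) * (dilation - 1)`, the span in pixels of a
#'   single dilated kernel application.
#' @export
effective_receptive_field <- function(kernel, dilation) {
  kernel + (kernel - 1) * (dilation - 1)
}
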