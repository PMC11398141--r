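# Minimal define-and-run neural-network engine.
#
# Feature maps are numeric 4-d arrays with dim c(H, W, N, C): height, width,
# batch, channels.  With R's column-major storage every (n, c) image plane and
# every channel block is contiguous, which the C++ convolution kernels and the
# vectorised per-channel reductions below both exploit.
#
# A module is an environment holding its parameters, cached activations from
# the last forward pass, and two closures: fwd(x, training) and bwd(grad),
# where bwd returns the gradient with respect to the module input and stores
# parameter gradients alongside each parameter (field "w" -> gradient "gw").

new_module <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$children <- list()
  self$param_names <- character()
  self$state_names <- character()
  self$decay_names <- character()
  class(self) <- c(type, "nn_module")
  self
}

#' Run a module forward
#'
#' Applies a network module to a feature map. Feature maps are numeric 4-d
#' arrays with dimensions `c(H, W, N, C)` (height, width, batch, channels).
#'
#' @param module A module created by one of the block constructors
#'   (e.g. [conv1_unit()], [hga()], [msfe()], [rheu_net()]).
#' @param x Input feature map, a 4-d numeric array.
#' @param training Logical; `TRUE` uses batch statistics in normalisation
#'   layers and samples dropout masks, `FALSE` uses running statistics.
#' @return The output feature map (4-d array). Modules cache what they need
#'   for [nn_backward()].
#' @export
nn_forward <- function(module, x, training = FALSE) {
  module$fwd(x, training)
}

#' Back-propagate through a module
#'
#' @param module A module previously run with [nn_forward()].
#' @param grad_out Gradient of a scalar loss with respect to the module
#'   output (same shape as that output).
#' @return Gradient with respect to the module input. Parameter gradients are
#'   stored in the module (field `w` gets gradient `gw`, etc.).
#' @export
nn_backward <- function(module, grad_out) {
  module$bwd(grad_out)
}

single_precision <- function() {
  isTRUE(getOption("rheunet.single_precision", FALSE))
}

#' List all sub-modules (depth first, self included)
#' @param module A network module.
#' @return A list of modules.
#' @export
nn_modules <- function(module) {
  out <- list(module)
  for (ch in module$children) out <- c(out, nn_modules(ch))
  out
}

#' Collect parameter references of a module tree
#'
#' @param module A network module.
#' @param prefix Internal; path prefix for names.
#' @return A named list; each element is `list(env, name)` pointing at one
#'   parameter array, so optimisers can update modules in place.
#' @export
nn_parameters <- function(module, prefix = "") {
  out <- list()
  for (nm in module$param_names) {
    out[[paste0(prefix, nm)]] <- list(env = module, name = nm)
  }
  chn <- names(module$children)
  for (i in seq_along(module$children)) {
    nm <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else sprintf("m%d", i)
    out <- c(out, nn_parameters(module$children[[i]], paste0(prefix, nm, ".")))
  }
  out
}

#' Total number of trainable parameters
#' @param module A network module.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(module) {
  ps <- nn_parameters(module)
  sum(vapply(ps, function(p) length(p$env[[p$name]]), numeric(1)))
}

#' Extract or restore the full state of a module tree
#'
#' The state contains every trainable parameter plus persistent buffers
#' (batch-norm running statistics), keyed by a stable path, so that
#' `nn_set_state(mod, nn_state(mod))` is an exact round trip. Used by
#' checkpointing and by best-epoch snapshots during training.
#'
#' @param module A network module.
#' @param prefix Internal path prefix.
#' @return Named list of numeric arrays.
#' @export
nn_state <- function(module, prefix = "") {
  out <- list()
  for (nm in c(module$param_names, module$state_names)) {
    out[[paste0(prefix, nm)]] <- module[[nm]]
  }
  chn <- names(module$children)
  for (i in seq_along(module$children)) {
    nm <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else sprintf("m%d", i)
    out <- c(out, nn_state(module$children[[i]], paste0(prefix, nm, ".")))
  }
  out
}

#' @rdname nn_state
#' @param state Named list as returned by `nn_state()`.
#' @export
nn_set_state <- function(module, state, prefix = "") {
  for (nm in c(module$param_names, module$state_names)) {
    key <- paste0(prefix, nm)
    if (is.null(state[[key]])) stop("state is missing entry ", key)
    module[[nm]] <- state[[key]]
  }
  chn <- names(module$children)
  for (i in seq_along(module$children)) {
    nm <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else sprintf("m%d", i)
    nn_set_state(module$children[[i]], state, paste0(prefix, nm, "."))
  }
  invisible(module)
}

# --- broadcast / reduction helpers on the (H, W, N, C) layout ---------------

check_fmap <- function(x, what = "x") {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) {
    stop(what, " must be a 4-d array with dim c(H, W, N, C)")
  }
  d
}

# expand a (1, 1, N, C) tensor over H x W
rep_nc <- function(v, H, W) {
  d <- dim(v)
  array(rep(as.vector(v), each = H * W), c(H, W, d[3L], d[4L]))
}

# expand a (H, W, N, 1) tensor over C channels
rep_hwn <- function(s, C) {
  d <- dim(s)
  array(rep(as.vector(s), times = C), c(d[1L], d[2L], d[3L], C))
}

# sum over H, W -> (1, 1, N, C)
sum_hw <- function(x) {
  d <- dim(x)
  array(colSums(matrix(x, nrow = d[1L] * d[2L])), c(1L, 1L, d[3L], d[4L]))
}

# sum over channels -> (H, W, N, 1)
sum_c <- function(x) {
  d <- dim(x)
  array(rowSums(matrix(x, ncol = d[4L])), c(d[1L], d[2L], d[3L], 1L))
}

# --- leaf layers -------------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, kernel = 3L, dilation = 1L,
                         groups = 1L, padding = NULL, bias = TRUE,
                         init_zero = FALSE, small = FALSE) {
  in_ch <- as.integer(in_ch); out_ch <- as.integer(out_ch)
  if (in_ch < 1L || out_ch < 1L) stop("channel counts must be positive")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("even kernel sizes are unsupported")
  if (in_ch %% groups != 0L || out_ch %% groups != 0L) {
    stop("channel counts must be divisible by groups")
  }
  if (is.null(padding)) padding <- dilation * (kernel - 1L) %/% 2L
  self <- new_module("layer_conv2d")
  self$in_ch <- in_ch; self$out_ch <- out_ch
  self$kernel <- kernel
  self$dilation <- as.integer(dilation)
  self$groups <- as.integer(groups)
  self$padding <- as.integer(padding)
  nw <- kernel * kernel * (in_ch %/% groups) * out_ch
  fan_in <- kernel * kernel * in_ch / groups
  self$w <- array(if (init_zero) rep(0, nw) else stats::rnorm(nw, sd = sqrt(2 / fan_in)),
                  dim = c(kernel, kernel, in_ch %/% groups, out_ch))
  self$param_names <- "w"
  self$decay_names <- "w"
  if (bias) {
    self$b <- numeric(out_ch)
    self$param_names <- c("w", "b")
  }
  self$small <- isTRUE(small) && groups == 1L
  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    if (d[4L] != self$in_ch) {
      stop(sprintf("input has %d channels but this convolution expects %d",
                   d[4L], self$in_ch))
    }
    self$x <- x
    if (self$small) {
      cpp_conv2d_small_forward(x, self$w, self$b, self$kernel, self$dilation,
                               self$padding)
    } else {
      cpp_conv2d_forward(x, self$w, self$b, self$kernel, self$dilation,
                         self$padding, self$groups, single_precision())
    }
  }
  self$bwd <- function(gy) {
    r <- if (self$small) {
      cpp_conv2d_small_backward(self$x, self$w, gy, !is.null(self$b),
                                self$kernel, self$dilation, self$padding)
    } else {
      cpp_conv2d_backward(self$x, self$w, gy, !is.null(self$b),
                          self$kernel, self$dilation, self$padding,
                          self$groups, single_precision())
    }
    self$gw <- r$gw
    if (!is.null(self$b)) self$gb <- r$gb
    r$gx
  }
  self
}

# Fused convolution + batch norm + activation: the conv1/conv2 unit of the
# residual blocks, computed in one C++ round trip. The im2col matrix and the
# normalised pre-activation are cached on the C++ side between forward and
# backward, so training steps never re-gather the input.
layer_conv_unit <- function(in_ch, out_ch, kernel = 3L, dilation = 1L,
                            padding = NULL,
                            activation = c("relu", "elu", "none"),
                            alpha = 1, eps = 1e-5, momentum = 0.1) {
  activation <- match.arg(activation)
  in_ch <- as.integer(in_ch); out_ch <- as.integer(out_ch)
  if (in_ch < 1L || out_ch < 1L) stop("channel counts must be positive")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("even kernel sizes are unsupported")
  if (is.null(padding)) padding <- dilation * (kernel - 1L) %/% 2L
  self <- new_module("layer_conv_unit")
  self$in_ch <- in_ch; self$out_ch <- out_ch
  self$kernel <- kernel
  self$dilation <- as.integer(dilation)
  self$padding <- as.integer(padding)
  self$act_code <- c(none = 0L, relu = 1L, elu = 2L)[[activation]]
  self$alpha <- alpha
  self$eps <- eps
  self$momentum <- momentum
  fan_in <- kernel * kernel * in_ch
  self$w <- array(stats::rnorm(kernel^2 * in_ch * out_ch, sd = sqrt(2 / fan_in)),
                  dim = c(kernel, kernel, in_ch, out_ch))
  self$gamma <- rep(1, out_ch)
  self$beta <- numeric(out_ch)
  self$running_mean <- numeric(out_ch)
  self$running_var <- rep(1, out_ch)
  self$param_names <- c("w", "gamma", "beta")
  self$decay_names <- "w"
  self$state_names <- c("running_mean", "running_var")
  self$need_input_grad <- TRUE
  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    if (d[4L] != self$in_ch) {
      stop(sprintf("input has %d channels but this unit expects %d",
                   d[4L], self$in_ch))
    }
    sp <- single_precision()
    old_cache <- if (identical(self$cache_single, sp)) self$cache else NULL
    r <- cpp_convunit_forward(x, self$w, self$gamma, self$beta,
                              self$running_mean, self$running_var, self$eps,
                              self$momentum, training, self$act_code,
                              self$alpha, self$kernel, self$dilation,
                              self$padding, training, sp, old_cache)
    if (training) {
      self$running_mean <- r$running_mean
      self$running_var <- r$running_var
    }
    self$cache <- r$cache
    self$cache_single <- sp
    self$train_mode <- training
    self$y <- r$y
    r$y
  }
  self$bwd <- function(gy) {
    if (!isTRUE(self$train_mode)) {
      stop("backward requires a preceding forward pass in training mode")
    }
    r <- cpp_convunit_backward(self$y, gy, self$w, self$gamma, self$cache,
                               self$act_code, self$alpha,
                               isTRUE(self$need_input_grad), self$cache_single)
    self$gw <- r$gw
    self$ggamma <- r$ggamma
    self$gbeta <- r$gbeta
    if (isTRUE(self$need_input_grad)) r$gx else NULL
  }
  self
}

layer_convt2x2 <- function(in_ch, out_ch, bias = TRUE) {
  self <- new_module("layer_convt2x2")
  self$in_ch <- as.integer(in_ch); self$out_ch <- as.integer(out_ch)
  fan_in <- 4 * in_ch
  self$w <- array(stats::rnorm(4 * in_ch * out_ch, sd = sqrt(2 / fan_in)),
                  dim = c(2L, 2L, in_ch, out_ch))
  self$param_names <- "w"
  self$decay_names <- "w"
  if (bias) {
    self$b <- numeric(out_ch)
    self$param_names <- c("w", "b")
  }
  self$fwd <- function(x, training = FALSE) {
    self$x <- x
    cpp_convt2x2_forward(x, self$w, self$b, single_precision())
  }
  self$bwd <- function(gy) {
    r <- cpp_convt2x2_backward(self$x, self$w, gy, !is.null(self$b),
                               single_precision())
    self$gw <- r$gw
    if (!is.null(self$b)) self$gb <- r$gb
    r$gx
  }
  self
}

layer_batchnorm2d <- function(channels, eps = 1e-5, momentum = 0.1) {
  self <- new_module("layer_batchnorm2d")
  self$channels <- as.integer(channels)
  self$eps <- eps
  self$momentum <- momentum
  self$gamma <- rep(1, channels)
  self$beta <- numeric(channels)
  self$running_mean <- numeric(channels)
  self$running_var <- rep(1, channels)
  self$param_names <- c("gamma", "beta")
  self$state_names <- c("running_mean", "running_var")
  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    R <- prod(d[1:3])
    m <- matrix(x, nrow = R)
    self$dims <- d
    self$train_mode <- training
    if (training) {
      mu <- colMeans(m)
      xc <- m - rep(mu, each = R)
      va <- colMeans(xc * xc)            # biased variance, as in normalisation
      inv <- 1 / sqrt(va + self$eps)
      xhat <- xc * rep(inv, each = R)
      corr <- if (R > 1) R / (R - 1) else 1
      self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * va * corr
      self$xhat <- xhat
      self$inv <- inv
      y <- xhat * rep(self$gamma, each = R) + rep(self$beta, each = R)
    } else {
      inv <- 1 / sqrt(self$running_var + self$eps)
      self$inv <- inv
      y <- (m - rep(self$running_mean, each = R)) * rep(self$gamma * inv, each = R) +
        rep(self$beta, each = R)
    }
    dim(y) <- d
    y
  }
  self$bwd <- function(gy) {
    d <- self$dims
    R <- prod(d[1:3])
    g <- matrix(gy, nrow = R)
    if (isTRUE(self$train_mode)) {
      xhat <- self$xhat
      self$ggamma <- colSums(g * xhat)
      self$gbeta <- colSums(g)
      gxh <- g * rep(self$gamma, each = R)
      gx <- (gxh - rep(colMeans(gxh), each = R) -
               xhat * rep(colMeans(gxh * xhat), each = R)) * rep(self$inv, each = R)
    } else {
      self$ggamma <- numeric(self$channels)
      self$gbeta <- colSums(g)
      gx <- g * rep(self$gamma * self$inv, each = R)
    }
    dim(gx) <- d
    gx
  }
  self
}

layer_relu <- function() {
  self <- new_module("layer_relu")
  self$fwd <- function(x, training = FALSE) {
    self$y <- cpp_relu_forward(x)
    self$y
  }
  self$bwd <- function(gy) cpp_relu_backward(self$y, gy)
  self
}

layer_elu <- function(alpha = 1) {
  self <- new_module("layer_elu")
  self$alpha <- alpha
  self$fwd <- function(x, training = FALSE) {
    self$y <- cpp_elu_forward(x, self$alpha)
    self$y
  }
  self$bwd <- function(gy) cpp_elu_backward(self$y, gy, self$alpha)
  self
}

layer_sigmoid <- function() {
  self <- new_module("layer_sigmoid")
  self$fwd <- function(x, training = FALSE) {
    self$y <- cpp_sigmoid_forward(x)
    self$y
  }
  self$bwd <- function(gy) gy * self$y * (1 - self$y)
  self
}

layer_dropout <- function(rate = 0.2) {
  self <- new_module("layer_dropout")
  self$rate <- rate
  self$fwd <- function(x, training = FALSE) {
    if (!training || self$rate <= 0) {
      self$mask <- NULL
      return(x)
    }
    keep <- 1 - self$rate
    m <- (stats::runif(length(x)) < keep) / keep
    dim(m) <- dim(x)
    self$mask <- m
    x * m
  }
  self$bwd <- function(gy) {
    if (is.null(self$mask)) gy else gy * self$mask
  }
  self
}

layer_maxpool2 <- function() {
  self <- new_module("layer_maxpool2")
  self$fwd <- function(x, training = FALSE) {
    r <- cpp_maxpool2_forward(x)
    self$xdim <- dim(x)
    self$argmax <- r$argmax
    r$y
  }
  self$bwd <- function(gy) {
    cpp_maxpool2_backward(gy, self$argmax, as.integer(self$xdim))
  }
  self
}

# global average pool over H, W -> (1, 1, N, C)
layer_gap <- function() {
  self <- new_module("layer_gap")
  self$fwd <- function(x, training = FALSE) {
    self$dims <- dim(x)
    sum_hw(x) / (self$dims[1L] * self$dims[2L])
  }
  self$bwd <- function(gy) {
    d <- self$dims
    rep_nc(gy, d[1L], d[2L]) / (d[1L] * d[2L])
  }
  self
}

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1L]]) && !inherits(mods[[1L]], "nn_module")) {
    mods <- mods[[1L]]
  }
  self <- new_module("nn_sequential")
  self$children <- mods
  self$fwd <- function(x, training = FALSE) {
    for (m in self$children) x <- m$fwd(x, training)
    x
  }
  self$bwd <- function(gy) {
    for (m in rev(self$children)) gy <- m$bwd(gy)
    gy
  }
  self
}
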