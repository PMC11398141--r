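# Full network assembly: residual encoder, MSFE bottleneck, residual decoder,
# HGA-gated skip connections, 2-channel sigmoid head, and the ablation grid.

#' Network configuration
#'
#' Describes one member of the ablation grid. With all three flags off the
#' result is a vanilla U-Net (double-conv stages, plain skips, double-conv
#' bottleneck); the full model enables residual blocks, HGA on every skip and
#' the MSFE bottleneck.
#'
#' @param in_channels Input channels; 3 for the 2.5D slice stack.
#' @param num_classes Output channels; 2 independent sigmoid channels
#'   (liver, tumor).
#' @param base_width Channels of the first encoder stage; stages double per
#'   level (64/128/256/512 with bottleneck 1024 at the defaults).
#' @param depth Number of encoder levels (default 4).
#' @param use_residual,use_hga,use_msfe Ablation flags.
#' @param dropout_rate Dropout after the bottleneck and the two deepest
#'   decoder stages (default 0.2).
#' @param hga_reduction Channel-attention reduction ratio (default 16).
#' @param seed RNG seed used for weight initialisation in [rheu_net()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 3L, num_classes = 2L,
                           base_width = 64L, depth = 4L,
                           use_residual = TRUE, use_hga = TRUE,
                           use_msfe = TRUE, dropout_rate = 0.2,
                           hga_reduction = 16L, seed = 1L) {
  stopifnot(depth >= 1, base_width >= 1, in_channels >= 1, num_classes >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 use_residual = isTRUE(use_residual),
                 use_hga = isTRUE(use_hga),
                 use_msfe = isTRUE(use_msfe),
                 dropout_rate = dropout_rate,
                 hga_reduction = as.integer(hga_reduction),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build the segmentation network
#'
#' Assembles the encoder-decoder: `depth` encoder stages at widths
#' `base_width * 2^(i-1)` with 2x2 max-pool downsampling, a bottleneck at
#' `base_width * 2^depth` (MSFE or a plain double convolution), a mirrored
#' decoder using 2x2 transposed-convolution upsampling, channel concatenation
#' of the (optionally HGA-gated) encoder skip with the upsampled decoder
#' feature, and a 1x1 convolution + sigmoid head with independent liver and
#' tumor channels. Weight initialisation is Kaiming-style and driven by
#' `config$seed`; building the same configuration twice gives identical
#' weights.
#'
#' @param config A [network_config()].
#' @return The network module. Run with [nn_forward()] (returns the
#'   probability map) or [rheu_forward()] (returns probabilities and logits).
#' @export
rheu_net <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  depth <- config$depth
  widths <- config$base_width * 2L^(seq_len(depth) - 1L)
  wb <- config$base_width * 2L^depth

  enc_block <- function(i_ch, o_ch) {
    if (config$use_residual) encoder_residual_block(i_ch, o_ch)
    else double_conv_block(i_ch, o_ch, "relu")
  }
  dec_block <- function(i_ch, o_ch) {
    if (config$use_residual) decoder_residual_block(i_ch, o_ch)
    else double_conv_block(i_ch, o_ch, "relu")
  }

  self <- new_module("rheu_net")
  self$config <- config
  children <- list()
  ins <- c(config$in_channels, widths[-depth])
  for (i in seq_len(depth)) {
    children[[paste0("enc", i)]] <- enc_block(ins[i], widths[i])
    children[[paste0("pool", i)]] <- layer_maxpool2()
  }
  children$bottleneck <- if (config$use_msfe) {
    msfe(msfe_config(widths[depth], branch_channels = wb, out_channels = wb))
  } else {
    nn_sequential(u1 = conv1_unit(conv_spec(widths[depth], wb)),
                  u2 = conv1_unit(conv_spec(wb, wb)))
  }
  children$drop_b <- layer_dropout(config$dropout_rate)
  prev <- wb
  for (i in rev(seq_len(depth))) {
    children[[paste0("up", i)]] <- layer_convt2x2(prev, widths[i])
    if (config$use_hga) {
      children[[paste0("hga", i)]] <- hga(widths[i], r = config$hga_reduction)
    }
    children[[paste0("dec", i)]] <- dec_block(2L * widths[i], widths[i])
    if (i >= depth - 1L) {
      children[[paste0("drop", i)]] <- layer_dropout(config$dropout_rate)
    }
    prev <- widths[i]
  }
  children$head <- layer_conv2d(widths[1L], config$num_classes, kernel = 1L,
                                bias = TRUE)
  children$enc1$children$u1$need_input_grad <- FALSE
  children$out_sig <- layer_sigmoid()
  self$children <- children

  self$fwd <- function(x, training = FALSE) {
    d <- check_fmap(x)
    mult <- 2L^depth
    if (d[1L] %% mult != 0L || d[2L] %% mult != 0L) {
      stop(sprintf("spatial dims %d x %d must be divisible by %d (depth %d)",
                   d[1L], d[2L], mult, depth))
    }
    if (d[4L] != config$in_channels) {
      stop(sprintf("input has %d channels, expected %d", d[4L], config$in_channels))
    }
    ch <- self$children
    skips <- vector("list", depth)
    cur <- x
    for (i in seq_len(depth)) {
      e <- ch[[paste0("enc", i)]]$fwd(cur, training)
      skips[[i]] <- e
      cur <- ch[[paste0("pool", i)]]$fwd(e, training)
    }
    cur <- ch$drop_b$fwd(ch$bottleneck$fwd(cur, training), training)
    self$skip_dims <- lapply(skips, dim)
    for (i in rev(seq_len(depth))) {
      u <- ch[[paste0("up", i)]]$fwd(cur, training)
      s <- if (config$use_hga) ch[[paste0("hga", i)]]$fwd(skips[[i]], training) else skips[[i]]
      cur <- ch[[paste0("dec", i)]]$fwd(cpp_cat_channels(s, u), training)
      if (i >= depth - 1L) {
        cur <- ch[[paste0("drop", i)]]$fwd(cur, training)
      }
    }
    logits <- ch$head$fwd(cur, training)
    self$logits <- logits
    ch$out_sig$fwd(logits, training)
  }

  self$bwd <- function(gy) {
    ch <- self$children
    g <- ch$head$bwd(ch$out_sig$bwd(gy))
    gskips <- vector("list", depth)
    for (i in seq_len(depth)) {
      if (i >= depth - 1L) g <- ch[[paste0("drop", i)]]$bwd(g)
      g <- ch[[paste0("dec", i)]]$bwd(g)
      ds <- self$skip_dims[[i]]
      parts <- cpp_split_channels(g, ds[4L])
      gskips[[i]] <- if (config$use_hga) ch[[paste0("hga", i)]]$bwd(parts$a) else parts$a
      g <- ch[[paste0("up", i)]]$bwd(parts$b)
    }
    g <- ch$bottleneck$bwd(ch$drop_b$bwd(g))
    for (i in rev(seq_len(depth))) {
      ge <- ch[[paste0("pool", i)]]$bwd(g) + gskips[[i]]
      g <- ch[[paste0("enc", i)]]$bwd(ge)
    }
    g
  }

  self
}

#' Forward pass returning probabilities and logits
#'
#' @param network A network from [rheu_net()].
#' @param x Input batch, a `(H, W, N, in_channels)` array with H and W
#'   divisible by `2^depth`.
#' @param training Logical; training or inference mode.
#' @return A list of class `segmentation_output` with elements
#'   `probabilities` and `logits`, both `(H, W, N, num_classes)` arrays;
#'   channel 1 is liver, channel 2 tumor.
#' @export
rheu_forward <- function(network, x, training = FALSE) {
  p <- network$fwd(x, training)
  structure(list(probabilities = p, logits = network$logits),
            class = "segmentation_output")
}

#' Binarise network output into masks and a composite label map
#'
#' Each class channel is thresholded independently; in the composite label
#' map tumor (2) overrides liver (1) where both channels fire, since tumors
#' lie inside the liver.
#'
#' @param output A `segmentation_output` from [rheu_forward()] or a
#'   probability array `(H, W, N, 2)`.
#' @param threshold Probability threshold in (0, 1), default 0.5.
#' @return A list with binary arrays `liver` and `tumor` (each `(H, W, N)`)
#'   and an integer `labels` array with values 0/1/2.
#' @export
predict_masks <- function(output, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  p <- if (inherits(output, "segmentation_output")) output$probabilities else output
  d <- check_fmap(p, "probabilities")
  if (d[4L] < 2L) stop("expected at least 2 class channels")
  H <- d[1L]; W <- d[2L]; N <- d[3L]
  n1 <- H * W * N
  v <- as.vector(p)
  liver <- array(v[seq_len(n1)] > threshold, c(H, W, N))
  tumor <- array(v[n1 + seq_len(n1)] > threshold, c(H, W, N))
  labels <- array(0L, c(H, W, N))
  labels[liver] <- 1L
  labels[tumor] <- 2L
  list(liver = liver, tumor = tumor, labels = labels)
}

#' Count sub-modules of a given type
#' @param network A network module.
#' @param type Module class name, e.g. `"hga"`.
#' @return Integer count.
#' @export
count_modules <- function(network, type) {
  sum(vapply(nn_modules(network), function(m) inherits(m, type), logical(1)))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single serialised file holding the network
#' configuration, the initialisation seed, and the full state (weights and
#' batch-norm running statistics); loading rebuilds the network and restores
#' the state exactly.
#'
#' @param network A network from [rheu_net()].
#' @param path File path.
#' @param extra Optional list stored alongside (e.g. training metadata).
#' @return `load_checkpoint()` returns a list with `network` and `extra`.
#' @export
save_checkpoint <- function(network, path, extra = list()) {
  saveRDS(list(config = network$config, seed = network$config$seed,
               state = nn_state(network), extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- rheu_net(ck$config)
  nn_set_state(net, ck$state)
  list(network = net, extra = ck$extra)
}
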