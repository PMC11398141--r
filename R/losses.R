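# Segmentation losses: Dice, binary cross-entropy, and their weighted sum.
# On 4-d feature maps the losses are computed per (batch item, channel) pair
# and averaged with equal weight, so liver and tumor channels contribute
# equally regardless of their pixel counts.

#' Loss configuration
#'
#' @param alpha Weight of the BCE term in the compound loss, in \[0, 1\]
#'   (default 0.5, which balances pixel-wise accuracy against region overlap).
#' @param epsilon Smoothing constant of the Dice ratio (default 1e-5).
#' @param clip Probability floor/ceiling applied before the BCE logs
#'   (default 1e-7, must lie in (0, 0.5)).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, epsilon = 1e-5, clip = 1e-7) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0, clip > 0, clip < 0.5)
  structure(list(alpha = alpha, epsilon = epsilon, clip = clip),
            class = "loss_config")
}

# split predictions/targets into per-(n, c) columns; plain vectors/matrices
# are treated as a single group
loss_columns <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y)) {
    stop(sprintf("prediction (%s) and target (%s) shapes differ",
                 paste(if (is.null(dim(x))) length(x) else dim(x), collapse = "x"),
                 paste(if (is.null(dim(y))) length(y) else dim(y), collapse = "x")))
  }
  d <- dim(x)
  if (!is.null(d) && length(d) == 4L) {
    list(x = matrix(x, nrow = d[1L] * d[2L]), y = matrix(y, nrow = d[1L] * d[2L]))
  } else {
    list(x = matrix(as.vector(x), ncol = 1L), y = matrix(as.vector(y), ncol = 1L))
  }
}

#' Dice loss
#'
#' `1 - (2 * sum(y * x) + eps) / (sum(y) + sum(x) + eps)`, computed per
#' channel and batch item and averaged. Zero for a perfect prediction and
#' bounded by 1.
#'
#' @param x Predicted probabilities in \[0, 1\] (vector or `(H, W, N, C)`
#'   array).
#' @param y Binary targets of the same shape.
#' @param epsilon Smoothing constant.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(x, y, epsilon = 1e-5) {
  cols <- loss_columns(x, y)
  num <- 2 * colSums(cols$x * cols$y) + epsilon
  den <- colSums(cols$x) + colSums(cols$y) + epsilon
  mean(1 - num / den)
}

# gradient of dice_loss w.r.t. x
dice_loss_grad <- function(x, y, epsilon = 1e-5) {
  cols <- loss_columns(x, y)
  A <- 2 * colSums(cols$x * cols$y) + epsilon
  B <- colSums(cols$x) + colSums(cols$y) + epsilon
  R <- nrow(cols$x)
  g <- -(2 * cols$y * rep(B, each = R) - rep(A, each = R)) /
    rep(B^2, each = R) / ncol(cols$x)
  if (!is.null(dim(x))) dim(g) <- dim(x) else g <- as.vector(g)
  g
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y * log(x) + (1 - y) * log(1 - x))` over all pixels, with `x`
#' clipped into `[clip, 1 - clip]` so the logs stay finite.
#'
#' @inheritParams dice_loss
#' @param clip Probability floor (default 1e-7).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(x, y, clip = 1e-7) {
  cols <- loss_columns(x, y)
  xc <- pmin(pmax(cols$x, clip), 1 - clip)
  -mean(cols$y * log(xc) + (1 - cols$y) * log(1 - xc))
}

bce_loss_grad <- function(x, y, clip = 1e-7) {
  cols <- loss_columns(x, y)
  xc <- pmin(pmax(cols$x, clip), 1 - clip)
  g <- (xc - cols$y) / (xc * (1 - xc)) / length(x)
  if (!is.null(dim(x))) dim(g) <- dim(x) else g <- as.vector(g)
  g
}

#' Compound BCE + Dice loss
#'
#' `alpha * bce_loss + (1 - alpha) * dice_loss`; the default `alpha = 0.5`
#' gives equal weight to pixel-level classification and region overlap. The
#' BCE term supplies stable gradients when both the target region and the
#' prediction are small, where the Dice term alone is unstable.
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
bce_dice_loss <- function(x, y, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  cfg$alpha * bce_loss(x, y, cfg$clip) +
    (1 - cfg$alpha) * dice_loss(x, y, cfg$epsilon)
}

bce_dice_loss_grad <- function(x, y, cfg = loss_config()) {
  cfg$alpha * bce_loss_grad(x, y, cfg$clip) +
    (1 - cfg$alpha) * dice_loss_grad(x, y, cfg$epsilon)
}
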