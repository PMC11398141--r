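# CT preprocessing: Hounsfield windowing, min-max scaling against the fixed
# window bounds, per-slice CLAHE, 2.5D slice stacking, and geometric
# augmentation. Volumes are arrays with dim c(H, W, S); the slice index is the
# last dimension, matching the NIfTI axis order used by the readers below.

#' Clip a CT volume to a Hounsfield window
#'
#' Voxels are clipped to `[level - width/2, level + width/2]`; the defaults
#' (width 200 HU, level 40 HU) give the soft-tissue window `[-60, 140]` that
#' makes liver parenchyma and hypodense lesions occupy most of the dynamic
#' range. Idempotent.
#'
#' @param v Numeric array of HU values (any shape).
#' @param width,level Window width and level in HU.
#' @return Array of the same shape, clipped.
#' @export
window_clip <- function(v, width = 200, level = 40) {
  stopifnot(width > 0)
  lo <- level - width / 2
  hi <- level + width / 2
  out <- pmin(pmax(v, lo), hi)
  attributes(out) <- attributes(v)
  out
}

#' Min-max normalisation against the window bounds
#'
#' Maps `[lower, upper]` linearly onto `[0, 1]`. The bounds default to the
#' soft-tissue window `[-60, 140]` rather than per-volume extremes, so
#' intensities are comparable across volumes; inputs are clipped first, which
#' makes the function safe on un-windowed data.
#'
#' @param v Numeric array.
#' @param lower,upper Fixed intensity bounds.
#' @return Array of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(v, lower = -60, upper = 140) {
  stopifnot(upper > lower)
  out <- (pmin(pmax(v, lower), upper) - lower) / (upper - lower)
  attributes(out) <- attributes(v)
  out
}

#' Contrast-limited adaptive histogram equalisation of one slice
#'
#' Thin wrapper around the CLAHE implementation in EBImage, applied to a
#' single 2-d slice already scaled to \[0, 1\]. Constant slices are returned
#' unchanged (their tile histograms are degenerate and carry no contrast to
#' redistribute).
#'
#' @param slice Numeric matrix with values in \[0, 1\].
#' @param clip_limit Histogram clip limit (default 2).
#' @param tiles Number of tiles per axis, `c(nx, ny)` (default 8 x 8).
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
clahe_equalize <- function(slice, clip_limit = 2, tiles = c(8L, 8L)) {
  stopifnot(is.matrix(slice))
  if (diff(range(slice)) == 0) {
    return(slice)
  }
  out <- EBImage::clahe(slice, nx = tiles[1L], ny = tiles[2L],
                        limit = clip_limit)
  out <- EBImage::imageData(out)
  pmin(pmax(out, 0), 1)
}

#' Full intensity preprocessing of a CT volume
#'
#' Window to `[level - width/2, level + width/2]`, min-max scale to \[0, 1\]
#' against those fixed bounds, then CLAHE per slice on the normalised data.
#'
#' @param v HU volume, array `(H, W, S)`.
#' @param width,level Hounsfield window (defaults 200 / 40).
#' @param use_clahe Apply CLAHE per slice (default `TRUE`).
#' @param clip_limit,tiles CLAHE parameters, see [clahe_equalize()].
#' @return Array `(H, W, S)` in \[0, 1\].
#' @export
preprocess_volume <- function(v, width = 200, level = 40, use_clahe = TRUE,
                              clip_limit = 2, tiles = c(8L, 8L)) {
  stopifnot(length(dim(v)) == 3L)
  out <- minmax_normalize(window_clip(v, width, level),
                          lower = level - width / 2, upper = level + width / 2)
  if (use_clahe) {
    for (i in seq_len(dim(out)[3L])) {
      out[, , i] <- clahe_equalize(out[, , i], clip_limit, tiles)
    }
  }
  out
}

#' Extract a 2.5D training sample
#'
#' The network input is the target slice stacked with its two neighbours as
#' channels (edges replicate the boundary slice); the target is the pair of
#' binary masks of the centre slice only: liver = label >= 1 (the anatomical
#' liver includes tumor voxels), tumor = label == 2.
#'
#' @param volume Preprocessed intensity volume `(H, W, S)` in \[0, 1\].
#' @param labels Integer label volume of the same shape, values 0/1/2.
#' @param i Centre slice index, `1 <= i <= S`.
#' @return List of class `slice25d` with `image` `(H, W, 3)` and `target`
#'   `(H, W, 2)`.
#' @export
stack_25d <- function(volume, labels, i) {
  d <- dim(volume)
  if (length(d) != 3L || d[3L] < 1L) stop("volume must be a non-empty (H, W, S) array")
  if (!identical(dim(labels), d)) stop("labels must match the volume shape")
  if (i < 1L || i > d[3L]) stop("slice index out of range")
  lo <- max(1L, i - 1L)
  hi <- min(d[3L], i + 1L)
  image <- array(c(volume[, , lo], volume[, , i], volume[, , hi]),
                 c(d[1L], d[2L], 3L))
  lab <- labels[, , i]
  target <- array(c(as.numeric(lab >= 1L), as.numeric(lab == 2L)),
                  c(d[1L], d[2L], 2L))
  structure(list(image = image, target = target, index = i), class = "slice25d")
}

rot90_left <- function(a) {
  # (H, W, C) -> counter-clockwise quarter turn
  d <- dim(a)
  aperm(a, c(2L, 1L, 3L))[d[2L]:1L, , , drop = FALSE]
}

rot90_right <- function(a) {
  d <- dim(a)
  aperm(a, c(2L, 1L, 3L))[, d[1L]:1L, , drop = FALSE]
}

reflect_pad_hw <- function(a, H2, W2) {
  d <- dim(a)
  ih <- c(seq_len(d[1L]), rev(seq_len(d[1L])))
  iw <- c(seq_len(d[2L]), rev(seq_len(d[2L])))
  ih <- rep_len(ih, H2)
  iw <- rep_len(iw, W2)
  a[ih, iw, , drop = FALSE]
}

#' Random geometric augmentation of a 2.5D sample
#'
#' Random crop to `crop_size`, then independent horizontal / vertical flips
#' (probability 0.5 each) and a quarter-turn rotation (probability 0.5, left
#' or right with equal chance). Image and target receive the identical
#' transform; samples smaller than the crop are reflect-padded first. Draws
#' from the global RNG, so results are reproducible under `set.seed()`.
#'
#' @param sample A `slice25d` from [stack_25d()].
#' @param crop_size Output side length in pixels (default 480; desk-scale
#'   work uses 96).
#' @param flip,rotate Enable the respective transforms.
#' @return A `slice25d` with `(crop_size, crop_size)` spatial dims.
#' @export
augment_sample <- function(sample, crop_size = 480L, flip = TRUE, rotate = TRUE) {
  stopifnot(inherits(sample, "slice25d"))
  img <- sample$image
  tgt <- sample$target
  d <- dim(img)
  S <- as.integer(crop_size)
  if (d[1L] < S || d[2L] < S) {
    img <- reflect_pad_hw(img, max(d[1L], S), max(d[2L], S))
    tgt <- reflect_pad_hw(tgt, max(d[1L], S), max(d[2L], S))
    d <- dim(img)
  }
  h0 <- if (d[1L] > S) sample.int(d[1L] - S + 1L, 1L) else 1L
  w0 <- if (d[2L] > S) sample.int(d[2L] - S + 1L, 1L) else 1L
  img <- img[h0:(h0 + S - 1L), w0:(w0 + S - 1L), , drop = FALSE]
  tgt <- tgt[h0:(h0 + S - 1L), w0:(w0 + S - 1L), , drop = FALSE]
  if (flip && stats::runif(1) < 0.5) {
    img <- img[S:1L, , , drop = FALSE]; tgt <- tgt[S:1L, , , drop = FALSE]
  }
  if (flip && stats::runif(1) < 0.5) {
    img <- img[, S:1L, , drop = FALSE]; tgt <- tgt[, S:1L, , drop = FALSE]
  }
  if (rotate && stats::runif(1) < 0.5) {
    if (stats::runif(1) < 0.5) {
      img <- rot90_left(img); tgt <- rot90_left(tgt)
    } else {
      img <- rot90_right(img); tgt <- rot90_right(tgt)
    }
  }
  structure(list(image = img, target = tgt, index = sample$index),
            class = "slice25d")
}

#' Choose training slice indices for one volume
#'
#' Keeps every slice whose liver mask is non-empty plus a fraction of the
#' empty ones, to limit trivially negative samples.
#'
#' @param labels Label volume `(H, W, S)`.
#' @param keep_empty_frac Fraction of liver-free slices to keep (default 0.1;
#'   sampled with the global RNG).
#' @return Integer vector of slice indices.
#' @export
select_training_slices <- function(labels, keep_empty_frac = 0.1) {
  S <- dim(labels)[3L]
  has_liver <- vapply(seq_len(S), function(i) any(labels[, , i] >= 1L), logical(1))
  keep <- which(has_liver)
  empty <- which(!has_liver)
  n_extra <- round(length(empty) * keep_empty_frac)
  if (n_extra > 0) {
    keep <- sort(c(keep, sample(empty, n_extra)))
  }
  keep
}

#' Volume-level train/validation split
#'
#' @param n Number of volumes.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Split seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_volumes <- function(n, train_frac = 0.8, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  idx <- sample.int(n)
  n_train <- max(1L, round(train_frac * n))
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[-seq_len(n_train)]))
}

#' Read / write volumes as NIfTI
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return `read_nifti_volume()` returns the array with a `spacing`
#'   attribute (mm per voxel along each axis).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' @rdname read_nifti_volume
#' @param v Array to write.
#' @param spacing Voxel spacing in mm (default from the `spacing` attribute,
#'   else 1).
#' @export
write_nifti_volume <- function(v, path, spacing = attr(v, "spacing")) {
  if (is.null(spacing)) spacing <- rep(1, length(dim(v)))
  arr <- array(as.vector(v), dim(v))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a preprocessed slice (or sample channel) as PNG for inspection
#'
#' @param mat Numeric matrix in \[0, 1\].
#' @param path Output PNG path.
#' @export
export_slice_png <- function(mat, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  png::writePNG(pmin(pmax(t(mat), 0), 1), path)
  invisible(path)
}
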