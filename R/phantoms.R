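# Synthetic CT phantoms: HU-valued volumes containing one ellipsoidal
# "liver" with 0-3 embedded lower-contrast "tumor" blobs, plus Gaussian
# noise, and the exactly matching 0/1/2 label volume. The phantoms exercise
# the whole pipeline (windowing, CLAHE, 2.5D stacking, training, metrics)
# with no external data; they emulate contrast and geometry, not anatomy.

#' Phantom specification
#'
#' Default intensities follow typical portal-venous abdominal CT: background
#' well below the soft-tissue window, liver parenchyma around 60 HU, and
#' hypodense lesions around 20 HU, so the standard window `[-60, 140]` clips
#' the background but keeps liver/tumor contrast. All geometric units are
#' voxels (slices for the z semi-axes).
#'
#' @param shape Volume shape as `c(slices, H, W)` (default `c(12, 96, 96)`).
#' @param liver_hu_mean,liver_hu_sd Liver tissue mean and per-voxel spread in
#'   HU (default 60 +- 10).
#' @param tumor_hu_mean,tumor_hu_sd Tumor tissue mean and spread (default
#'   20 +- 10); must be hypodense relative to the liver unless
#'   `hyperdense = TRUE`.
#' @param background_hu Background intensity (default -100).
#' @param noise_sd Additional additive Gaussian noise in HU (default 5).
#' @param n_tumors Inclusive integer range for the tumor count (default 0-3).
#' @param tumor_radius In-plane tumor semi-axis range in voxels.
#' @param tumor_z_radius Through-plane tumor semi-axis range in slices.
#' @param liver_radius In-plane liver semi-axis range.
#' @param liver_z_radius Through-plane liver semi-axis range.
#' @param spacing Voxel spacing `(x, y, z)` in mm (default 1 x 1 x 5).
#' @param hyperdense If `TRUE`, tumors brighter than liver are allowed.
#' @param seed Default seed used by [generate_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12L, 96L, 96L),
                         liver_hu_mean = 60, liver_hu_sd = 10,
                         tumor_hu_mean = 20, tumor_hu_sd = 10,
                         background_hu = -100, noise_sd = 5,
                         n_tumors = c(0L, 3L),
                         tumor_radius = c(3.5, 9),
                         tumor_z_radius = c(1, 2.2),
                         liver_radius = c(20, 30),
                         liver_z_radius = c(2.5, 3.5),
                         spacing = c(1, 1, 5),
                         hyperdense = FALSE, seed = 1L) {
  stopifnot(length(shape) == 3L, shape[1L] >= 3L, shape[2L] >= 32L, shape[3L] >= 32L)
  if (!hyperdense && tumor_hu_mean >= liver_hu_mean) {
    stop("tumors must be hypodense (tumor_hu_mean < liver_hu_mean) unless hyperdense = TRUE")
  }
  structure(list(shape = as.integer(shape),
                 liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
                 tumor_hu_mean = tumor_hu_mean, tumor_hu_sd = tumor_hu_sd,
                 background_hu = background_hu, noise_sd = noise_sd,
                 n_tumors = as.integer(n_tumors),
                 tumor_radius = tumor_radius,
                 tumor_z_radius = tumor_z_radius,
                 liver_radius = liver_radius,
                 liver_z_radius = liver_z_radius,
                 spacing = spacing,
                 hyperdense = isTRUE(hyperdense),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

#' Generate one CT phantom
#'
#' Places a randomly posed (shifted, scaled, in-plane rotated) liver
#' ellipsoid on a dark background, embeds `n_tumors` ellipsoidal lesions
#' strictly inside the liver mask (bounded rejection sampling; an explicit
#' error is raised if the geometry is infeasible after 50 retries per
#' lesion), fills each region with Gaussian tissue intensities, and adds
#' global Gaussian noise. Labels exactly match the generating geometry, with
#' tumor (2) overriding liver (1). Bit-identical for identical seeds.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return List of class `ct_phantom` with `volume` (HU array `(H, W, S)`
#'   with a `spacing` attribute), `labels` (integer array, same shape),
#'   `spec` and `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$shape[1L]; H <- spec$shape[2L]; W <- spec$shape[3L]
  with_seed(seed, {
    hh <- rep(seq_len(H), times = W * S)
    ww <- rep(rep(seq_len(W), each = H), times = S)
    zz <- rep(seq_len(S), each = H * W)

    ch <- H / 2 + stats::runif(1, -H / 12, H / 12)
    cw <- W / 2 + stats::runif(1, -W / 12, W / 12)
    cz <- S / 2 + stats::runif(1, -S / 12, S / 12)
    a <- stats::runif(1, spec$liver_radius[1L], spec$liver_radius[2L])
    b <- stats::runif(1, spec$liver_radius[1L], spec$liver_radius[2L])
    cc <- stats::runif(1, spec$liver_z_radius[1L], spec$liver_z_radius[2L])
    th <- stats::runif(1, 0, pi)
    dh <- hh - ch; dw <- ww - cw
    u <- dh * cos(th) + dw * sin(th)
    v <- -dh * sin(th) + dw * cos(th)
    liver <- (u / a)^2 + (v / b)^2 + ((zz - cz) / cc)^2 <= 1
    liver_idx <- which(liver)
    if (length(liver_idx) == 0) stop("liver ellipsoid fell outside the volume")

    labels <- integer(H * W * S)
    labels[liver] <- 1L

    n_t <- if (spec$n_tumors[1L] == spec$n_tumors[2L]) spec$n_tumors[1L] else
      sample(seq(spec$n_tumors[1L], spec$n_tumors[2L]), 1L)
    for (k in seq_len(n_t)) {
      placed <- FALSE
      for (try in seq_len(50L)) {
        ctr <- liver_idx[sample.int(length(liver_idx), 1L)]
        th0 <- hh[ctr]; tw0 <- ww[ctr]; tz0 <- zz[ctr]
        rt <- stats::runif(1, spec$tumor_radius[1L], spec$tumor_radius[2L])
        rz <- stats::runif(1, spec$tumor_z_radius[1L], spec$tumor_z_radius[2L])
        tum <- ((hh - th0) / rt)^2 + ((ww - tw0) / rt)^2 + ((zz - tz0) / rz)^2 <= 1
        if (any(tum) && all(liver[tum])) {
          labels[tum] <- 2L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place a tumor inside the liver after 50 retries; ",
             "tumor radii are infeasible for this liver geometry")
      }
    }

    vol <- rep(spec$background_hu, H * W * S)
    is_liver <- labels == 1L
    is_tumor <- labels == 2L
    if (spec$liver_hu_sd > 0) {
      vol[is_liver] <- stats::rnorm(sum(is_liver), spec$liver_hu_mean, spec$liver_hu_sd)
    } else {
      vol[is_liver] <- spec$liver_hu_mean
    }
    if (spec$tumor_hu_sd > 0) {
      vol[is_tumor] <- stats::rnorm(sum(is_tumor), spec$tumor_hu_mean, spec$tumor_hu_sd)
    } else {
      vol[is_tumor] <- spec$tumor_hu_mean
    }
    if (spec$noise_sd > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
    }
    vol <- array(vol, c(H, W, S))
    attr(vol, "spacing") <- spec$spacing
    structure(list(volume = vol, labels = array(labels, c(H, W, S)),
                   spec = spec, seed = as.integer(seed)),
              class = "ct_phantom")
  })
}

#' Generate a phantom dataset
#'
#' Per-volume seeds are `seed + 0:(n-1)`, so any volume can be regenerated
#' independently. With `dir = NULL` the volumes are returned in memory;
#' otherwise NIfTI pairs (`img_###.nii.gz`, `lbl_###.nii.gz`) are written
#' together with a JSON manifest that records the spec and the seeds and
#' allows exact regeneration.
#'
#' @param n Number of volumes.
#' @param spec A [phantom_spec()].
#' @param seed Base seed.
#' @param dir Output directory, or `NULL` for in-memory.
#' @return In-memory: a list of `ct_phantom`s. On disk: the manifest path,
#'   invisibly.
#' @export
generate_phantom_dataset <- function(n, spec = phantom_spec(), seed = 1L,
                                     dir = NULL) {
  stopifnot(n >= 1)
  seeds <- as.integer(seed) + seq_len(n) - 1L
  phantoms <- lapply(seeds, function(s) generate_phantom(spec, seed = s))
  if (is.null(dir)) {
    return(phantoms)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(n)) {
    write_nifti_volume(phantoms[[i]]$volume,
                       file.path(dir, sprintf("img_%03d.nii.gz", i)),
                       spacing = spec$spacing)
    write_nifti_volume(phantoms[[i]]$labels,
                       file.path(dir, sprintf("lbl_%03d.nii.gz", i)),
                       spacing = spec$spacing)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n = n, seed = as.integer(seed), seeds = seeds,
                            spec = unclass(spec)),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Regenerate a phantom dataset from its manifest
#'
#' @param manifest Path to a `manifest.json` written by
#'   [generate_phantom_dataset()].
#' @param dir Output directory (defaults to the manifest's directory).
#' @return The manifest path, invisibly.
#' @export
regenerate_from_manifest <- function(manifest, dir = dirname(manifest)) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  spec <- do.call(phantom_spec, m$spec[setdiff(names(m$spec), "seed")])
  spec$seed <- as.integer(m$spec$seed)
  generate_phantom_dataset(m$n, spec = spec, seed = m$seed, dir = dir)
}

#' Read a phantom dataset from disk
#'
#' @param dir Directory written by [generate_phantom_dataset()].
#' @return List of lists with `volume` and `labels` arrays.
#' @export
read_phantom_dataset <- function(dir) {
  imgs <- sort(list.files(dir, "^img_.*\\.nii(\\.gz)?$", full.names = TRUE))
  lbls <- sort(list.files(dir, "^lbl_.*\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0 || length(imgs) != length(lbls)) {
    stop("directory does not contain a matching img_/lbl_ NIfTI set")
  }
  unname(Map(function(iv, lv) {
    lab <- read_nifti_volume(lv)
    list(volume = read_nifti_volume(iv),
         labels = array(as.integer(round(lab)), dim(lab)))
  }, imgs, lbls))
}
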