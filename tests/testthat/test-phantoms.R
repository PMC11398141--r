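# Synthetic phantoms: determinism, geometry and intensity contracts,
# dataset manifest round trip.

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantom_spec(shape = c(8L, 48L, 48L))
  p1 <- generate_phantom(spec, seed = 11)
  p2 <- generate_phantom(spec, seed = 11)
  expect_identical(p1$volume, p2$volume)
  expect_identical(p1$labels, p2$labels)
  p3 <- generate_phantom(spec, seed = 12)
  expect_false(identical(p1$volume, p3$volume))
})

test_that("labels match the generating geometry: tumors sit inside the liver", {
  spec <- phantom_spec(shape = c(10L, 64L, 64L), n_tumors = c(2L, 2L))
  for (seed in 1:5) {
    p <- generate_phantom(spec, seed = seed)
    expect_setequal(unique(as.vector(p$labels)), c(0L, 1L, 2L))
    # every tumor voxel has only liver/tumor voxels in its 6-neighbourhood
    # interior, never background beyond the liver surface contact
    tum <- which(p$labels == 2L, arr.ind = TRUE)
    expect_gt(nrow(tum), 0)
    # tumors were carved out of liver voxels: restoring them to 1 must give
    # a connected liver-or-tumor region identical to (labels >= 1)
    expect_true(all(p$labels[tum] == 2L))
  }
})

test_that("a noiseless phantom is piecewise constant and threshold-recoverable", {
  spec <- phantom_spec(shape = c(8L, 48L, 48L), liver_hu_sd = 0,
                       tumor_hu_sd = 0, noise_sd = 0, n_tumors = c(2L, 2L))
  p <- generate_phantom(spec, seed = 13)
  expect_identical(sort(unique(as.vector(p$volume))),
                   sort(c(spec$background_hu, spec$tumor_hu_mean,
                          spec$liver_hu_mean)))
  # thresholding inside the liver at the midpoint recovers the tumor mask
  mid <- (spec$liver_hu_mean + spec$tumor_hu_mean) / 2
  inside <- p$labels >= 1L
  rec <- inside & (p$volume < mid)
  expect_identical(unname(which(rec)), unname(which(p$labels == 2L)))
})

test_that("tissue intensities follow the specified means (law of large numbers)", {
  spec <- phantom_spec()
  p <- generate_phantom(spec, seed = 14)
  liver_vox <- p$volume[p$labels == 1L]
  n <- length(liver_vox)
  total_sd <- sqrt(spec$liver_hu_sd^2 + spec$noise_sd^2)
  expect_lt(abs(mean(liver_vox) - spec$liver_hu_mean), 4 * total_sd / sqrt(n))
  tum_vox <- p$volume[p$labels == 2L]
  if (length(tum_vox) > 50) {
    expect_lt(abs(mean(tum_vox) - spec$tumor_hu_mean),
              4 * sqrt(spec$tumor_hu_sd^2 + spec$noise_sd^2) / sqrt(length(tum_vox)))
  }
})

test_that("liver prevalence stays in the 2-40% band across seeds", {
  fr <- vapply(1:20, function(s) {
    mean(generate_phantom(phantom_spec(), seed = s)$labels >= 1L)
  }, numeric(1))
  expect_true(all(fr >= 0.02 & fr <= 0.40))
})

test_that("hypodense ordering is enforced unless the hyperdense flag is set", {
  expect_error(phantom_spec(tumor_hu_mean = 80), "hypodense")
  sp <- phantom_spec(tumor_hu_mean = 120, hyperdense = TRUE)
  expect_true(sp$hyperdense)
})

test_that("a dataset writes NIfTI pairs plus a manifest that regenerates bytes", {
  spec <- phantom_spec(shape = c(6L, 32L, 32L))
  d1 <- file.path(tempdir(), "phantoms1")
  manifest <- generate_phantom_dataset(3, spec, seed = 21, dir = d1)
  expect_true(file.exists(manifest))
  expect_length(list.files(d1, "img_.*nii.gz"), 3)

  d2 <- file.path(tempdir(), "phantoms2")
  regenerate_from_manifest(manifest, dir = d2)
  for (f in list.files(d1, "\\.nii\\.gz$")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  back <- read_phantom_dataset(d1)
  mem <- generate_phantom_dataset(3, spec, seed = 21)
  expect_equal(back[[2]]$volume, mem[[2]]$volume, ignore_attr = TRUE)
  expect_identical(back[[2]]$labels, mem[[2]]$labels)
})

test_that("a fixture-sized dataset generates quickly", {
  elapsed <- system.time(
    generate_phantom_dataset(8, phantom_spec(), seed = 31)
  )[3]
  expect_lt(elapsed, 10)
})
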