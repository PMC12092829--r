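test_that("anisotropy correction is the identity on isotropic volumes", {
  raw <- random_raw(c(6, 6, 6), seed = 1)
  expect_identical(correct_anisotropy(raw)$data, raw$data)
})

test_that("anisotropy correction duplicates slices per the index-mapping rule", {
  raw <- random_raw(c(5, 8, 8), seed = 2, spacing = voxel_spacing(2, 1, 1))
  out <- correct_anisotropy(raw)
  expect_identical(dim(out), c(10L, 8L, 8L))
  expect_true(is_isotropic(out$spacing))
  # i_in = floor(i_out * dz_out / dz_in), 0-based
  for (i in 0:9)
    expect_identical(out$data[i + 1, , ], raw$data[floor(i / 2) + 1, , ])
})

test_that("degrade-then-correct restores the z extent voxel-for-voxel", {
  for (factor in c(2L, 3L)) {
    raw <- random_raw(c(12, 8, 8), seed = factor)
    deg <- degrade_anisotropic(raw, factor)
    cor <- correct_anisotropy(deg)
    expect_identical(dim(cor), dim(raw))
    # nearest-neighbour oracle: corrected slice i duplicates the kept slice
    for (i in 0:11) {
      kept <- floor(i / factor)  # index into the degraded stack, 0-based
      expect_identical(cor$data[i + 1, , ], deg$data[kept + 1, , ])
    }
  }
})

test_that("nearest-neighbour resampling never creates new intensity values", {
  v <- array(sample(c(0L, 7L, 255L), 5 * 8 * 8, TRUE), c(5, 8, 8))
  raw <- raw_volume(v, spacing = voxel_spacing(2, 1, 1))
  out <- correct_anisotropy(raw)
  expect_true(all(unique(as.vector(out$data)) %in% c(0L, 7L, 255L)))
  rs <- resize_to_cube(raw_volume(v), 16)
  expect_true(all(unique(as.vector(rs$data)) %in% c(0L, 7L, 255L)))
})

test_that("cube resize duplicates voxels 2x per axis when doubling", {
  v <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  raw <- raw_volume(v)
  out <- resize_to_cube(raw, 32)
  expect_identical(dim(out), c(32L, 32L, 32L))
  ok <- TRUE
  for (i in 0:31) for (j in 0:31) for (k in 0:31)
    ok <- ok && out$data[i + 1, j + 1, k + 1] ==
      v[floor(i / 2) + 1, floor(j / 2) + 1, floor(k / 2) + 1]
  expect_true(ok)
  expect_identical(resize_to_cube(raw, 16)$data, v)  # identity at same size
})

test_that("label volumes resize with the same operator and keep their value set", {
  lab <- random_labels(c(6, 9, 12), seed = 3)
  out <- resize_to_cube(lab, 16)
  expect_s3_class(out, "sbf_labels")
  expect_true(all(unique(as.vector(out$data)) %in% unique(as.vector(lab$data))))
})

test_that("normalization divides by 255 exactly once", {
  v <- array(c(0L, 51L, 255L, 128L), c(4, 1, 1))
  norm <- normalize_volume(raw_volume(v))
  expect_equal(as.vector(norm$data), c(0, 0.2, 1, 128 / 255))
  expect_true(norm$normalized)
  expect_error(normalize_volume(norm), "already normalized")
})

test_that("bilateral filter leaves constant volumes unchanged and contracts the range", {
  flat <- raw_volume(array(80L, c(4, 10, 10)))
  expect_equal(denoise_bilateral(flat)$data, flat$data)
  noisy <- random_raw(c(4, 12, 12), seed = 8)
  out <- denoise_bilateral(noisy)
  expect_gte(min(out$data), min(noisy$data))
  expect_lte(max(out$data), max(noisy$data))
  expect_error(denoise_bilateral(noisy, sigma_spatial = 0), "sigma")
})

test_that("bilateral filter approaches a pure Gaussian blur as sigma_range grows", {
  noisy <- random_raw(c(1, 9, 9), seed = 9)
  sigma <- 1.5
  out <- denoise_bilateral(noisy, sigma_spatial = sigma, sigma_range = 1e9)
  oracle <- bf_gaussian_blur(noisy$data[1, , ], sigma,
                             radius = ceiling(2 * sigma))
  expect_lt(max(abs(out$data[1, , ] - oracle)), 1e-6)
})

test_that("bilateral filter strictly reduces an isolated salt voxel", {
  v <- array(50, c(1, 9, 9))
  v[1, 5, 5] <- 250
  out <- denoise_bilateral(raw_volume(v), sigma_spatial = 2, sigma_range = 60)
  expect_lt(out$data[1, 5, 5], 250)
  expect_gt(out$data[1, 5, 5], 50)
})

test_that("reslice/unreslice round trip is bit-identical on every axis", {
  raw <- random_raw(c(4, 5, 6), seed = 10)
  for (ax in c("z", "y", "x")) {
    b <- reslice(raw, ax)
    expect_identical(unreslice(b)$data, raw$data)
  }
  lab <- random_labels(c(4, 5, 6), seed = 11)
  for (ax in c("z", "y", "x"))
    expect_identical(unreslice(reslice(lab, ax))$data, lab$data)
})

test_that("reslice shapes and index bookkeeping are correct", {
  raw <- random_raw(c(4, 5, 6), seed = 12)
  bz <- reslice(raw, "z")
  expect_length(bz$slices, 4)
  expect_identical(dim(bz$slices[[1]]), c(5L, 6L))
  # single nonzero voxel at (z,y,x) = (2,3,4) appears in slice index 3 along y
  v <- array(0L, c(6, 6, 6))
  v[2, 3, 4] <- 200L
  by <- reslice(raw_volume(v), "y")
  expect_equal(by$slices[[3]][2, 4], 200)
  expect_true(all(vapply(by$slices[-3], function(s) all(s == 0), logical(1))))
})

test_that("reslice refuses anisotropic volumes", {
  raw <- random_raw(c(4, 4, 4), spacing = voxel_spacing(2, 1, 1))
  expect_error(reslice(raw, "y"), "isotropic")
})

test_that("tri-axial augmentation emits 3 x side section pairs per cube", {
  mk <- function(side, seed) {
    ph <- list(raw = random_raw(c(side, side, side), seed = seed),
               labels = random_labels(c(side, side, side), seed = seed + 1))
    ph
  }
  one <- augment_training_set(list(mk(64, 1)))
  expect_length(one, 3 * 64)
  two <- augment_training_set(list(mk(16, 2), mk(16, 3)))
  expect_length(two, 2 * 3 * 16)
  expect_length(augment_training_set(list()), 0)
  # sections carry matched image/label pairs
  expect_identical(dim(one[[1]]$image), dim(one[[1]]$label))
  # mismatched shapes are rejected
  bad <- list(raw = random_raw(c(16, 16, 16)),
              labels = random_labels(c(16, 16, 8)))
  expect_error(augment_training_set(list(bad)))
})
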