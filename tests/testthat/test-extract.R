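sphere_array <- function(dims, ctr, r) {
  g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                   x = seq_len(dims[3]))
  array((g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <= r^2, dims)
}

test_that("the distance transform is exact against a brute-force oracle", {
  withr::with_seed(13, {
    m <- array(runif(10 * 11 * 12) > 0.6, c(10, 11, 12))
  })
  d <- sqrt(sbfseg:::.edt3d_sq(m))
  expect_true(all(d[!m] == 0))
  expect_true(all(d[m] > 0))
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  for (r in sample(nrow(fg), 25)) {
    bf <- sqrt(min((bg[, 1] - fg[r, 1])^2 + (bg[, 2] - fg[r, 2])^2 +
                     (bg[, 3] - fg[r, 3])^2))
    expect_equal(d[fg[r, 1], fg[r, 2], fg[r, 3]], bf)
  }
})

test_that("the default masker recovers phantom-scene foreground", {
  sc <- generate_scene(scene_spec(n_cells = 2, seed = 19))
  mask <- mask_foreground(sc$raw)
  truth <- sc$instances$data > 0
  expect_gte(sum(mask$data & truth) / sum(truth), 0.95)
  expect_lte(sum(mask$data & !truth) / sum(!truth), 0.05)
  expect_equal(mask$provenance, "threshold")
})

test_that("degenerate volumes give empty masks", {
  zero <- raw_volume(array(0L, c(4, 8, 8)))
  expect_false(any(mask_foreground(zero)$data))
  const <- raw_volume(array(120L, c(4, 8, 8)))
  expect_message(m <- mask_foreground(const), "bimodality")
  expect_false(any(m$data))
})

test_that("an external masker is applied per section and validated", {
  sc <- generate_scene(scene_spec(n_cells = 1, seed = 23))
  thr <- otsu_threshold(as.vector(sc$raw$data))
  mask <- mask_foreground(sc$raw, masker = function(sl) sl > thr)
  expect_equal(mask$provenance, "external-masker")
  expect_gt(mean(mask$data[sc$instances$data > 0]), 0.9)
  expect_error(mask_foreground(sc$raw, masker = function(sl) sl[1:2, 1:2] > 0),
               "masker")
})

test_that("watershed separates two disjoint spheres into two instances", {
  m <- sphere_array(c(30, 16, 16), c(9, 8, 8), 5) |
    sphere_array(c(30, 16, 16), c(23, 8, 8), 5)
  inst <- watershed_cells(m, min_seed_distance = 5)
  expect_equal(inst$n_instances, 2L)
  # each sphere is exactly one instance
  expect_length(unique(inst$data[sphere_array(c(30, 16, 16), c(9, 8, 8), 5)]), 1)
  expect_length(unique(inst$data[sphere_array(c(30, 16, 16), c(23, 8, 8), 5)]), 1)
  # partition property: instances cover the mask and only the mask
  expect_identical(inst$data > 0, m)
})

test_that("one sphere gives one instance; an empty mask gives zero", {
  m <- sphere_array(c(16, 16, 16), c(8, 8, 8), 5)
  expect_equal(watershed_cells(m, 5)$n_instances, 1L)
  expect_equal(watershed_cells(array(FALSE, c(5, 5, 5)))$n_instances, 0L)
})

test_that("two spheres fused by a thin neck split near the neck", {
  dims <- c(36, 18, 18)
  m <- sphere_array(dims, c(13, 9, 9), 7) | sphere_array(dims, c(23, 9, 9), 7)
  inst <- watershed_cells(m, min_seed_distance = 6, h = 1.5)
  expect_equal(inst$n_instances, 2L)
  # the split surface lies in the neck region between the two centres
  lab_a <- inst$data[13, 9, 9]
  lab_b <- inst$data[23, 9, 9]
  expect_true(lab_a != lab_b)
  last_a <- max(which(apply(inst$data == lab_a, 1, any)))
  first_b <- min(which(apply(inst$data == lab_b, 1, any)))
  expect_gte(last_a, 15)   # split surface lies in the neck region
  expect_lte(last_a, 21)
  expect_equal(first_b, last_a + 1L)
})

test_that("watershed agrees with an independent tolerance-based implementation", {
  dims <- c(30, 16, 16)
  m <- sphere_array(dims, c(9, 8, 8), 5) | sphere_array(dims, c(22, 8, 8), 5)
  inst <- watershed_cells(m, min_seed_distance = 5)
  d <- sqrt(sbfseg:::.edt3d_sq(m))
  ref <- EBImage::watershed(d, tolerance = 1)
  expect_equal(length(setdiff(unique(as.vector(ref)), 0)), inst$n_instances)
  # identical partition up to label names
  agree <- mapply(function(a, b) a > 0 && b > 0, inst$data, ref)
  tab <- table(inst$data[inst$data > 0], as.vector(ref)[inst$data > 0])
  expect_equal(sum(apply(tab, 1, max)), sum(inst$data > 0))
})

test_that("crops cover their instance with margin arithmetic and clamping", {
  v <- array(10L, c(20, 20, 20))
  inst <- array(0L, c(20, 20, 20))
  inst[5:14, 3:12, 9:18] <- 1L
  v[inst == 1L] <- 200L
  crops <- crop_cells(raw_volume(v), instance_volume(inst), margin = 2)
  expect_length(crops, 1)
  expect_equal(crops[[1]]$bbox[, "lo"], c(3, 1, 7), ignore_attr = TRUE)
  expect_equal(crops[[1]]$bbox[, "hi"], c(16, 14, 20), ignore_attr = TRUE)
  expect_identical(dim(crops[[1]]$volume$data), c(14L, 14L, 14L))
  expect_error(crop_cells(raw_volume(v), instance_volume(inst), margin = -1),
               "margin")
  none <- crop_cells(raw_volume(v), instance_volume(array(0L, c(20, 20, 20))))
  expect_length(none, 0)
})

test_that("neighbouring instances are blanked to background inside a crop", {
  v <- array(10L, c(10, 24, 10))
  inst <- array(0L, c(10, 24, 10))
  inst[3:8, 3:10, 3:8] <- 1L
  inst[3:8, 12:19, 3:8] <- 2L
  v[inst > 0L] <- 220L
  crops <- crop_cells(raw_volume(v), instance_volume(inst), margin = 3)
  c1 <- crops[[1]]
  # the second instance intrudes into the margin of the first crop; its
  # voxels must be background intensity there
  sub_inst <- inst[c1$bbox[1, 1]:c1$bbox[1, 2], c1$bbox[2, 1]:c1$bbox[2, 2],
                   c1$bbox[3, 1]:c1$bbox[3, 2]]
  expect_true(any(sub_inst == 2L))
  expect_true(all(c1$volume$data[sub_inst == 2L] == 10))
  expect_true(all(c1$volume$data[sub_inst == 1L] == 220))
})

test_that("the extraction pipeline isolates each cell of a synthetic scene", {
  sc <- generate_scene(scene_spec(n_cells = 3, min_gap = 6,
                                  volume_shape = c(80L, 120L, 120L),
                                  seed = 27))
  res <- extract_pipeline(sc$raw, min_seed_distance = 10)
  expect_equal(res$instances$n_instances, 3L)
  expect_length(res$crops, 3)
  expect_equal(res$manifest$n_cells, 3L)
  # instance-majority: each crop contains exactly one true cell's voxels
  for (cr in res$crops) {
    b <- cr$bbox
    ids <- setdiff(unique(as.vector(
      sc$instances$data[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]])), 0L)
    main <- ids[which.max(vapply(ids, function(i)
      sum(sc$instances$data[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                            b[3, 1]:b[3, 2]] == i), numeric(1)))]
    expect_equal(sum(sc$instances$data[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                                       b[3, 1]:b[3, 2]] == main),
                 sum(sc$instances$data == main))
  }
  # instances live only inside the mask and cover the masked cell bodies;
  # sub-seed debris blobs in the mask legitimately stay unlabelled
  expect_true(all(res$instances$data[!res$mask$data] == 0))
  cellmask <- res$mask$data & sc$instances$data > 0
  expect_gt(mean(res$instances$data[cellmask] > 0), 0.999)
})
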