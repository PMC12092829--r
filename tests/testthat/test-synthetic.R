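test_that("degenerate phantom with no organelles contains only background and cytoplasm", {
  spec <- phantom_spec(stage = 1, organelle_fractions = c(
    plastid = 0, mitochondrion = 0, peroxisome = 0, nucleus = 0), seed = 5)
  ph <- generate_phantom(spec)
  expect_identical(sort(unique(as.vector(ph$labels$data))), c(0L, 1L))
})

test_that("phantom generation is bit-identical for a repeated seed", {
  a <- generate_phantom(phantom_spec(stage = 3, seed = 9))
  b <- generate_phantom(phantom_spec(stage = 3, seed = 9))
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$labels$data, b$labels$data)
  c <- generate_phantom(phantom_spec(stage = 3, seed = 10))
  expect_false(identical(a$raw$data, c$raw$data))
})

test_that("organelle component counts follow the division stage", {
  # one body per organelle before division, two per daughter afterwards
  for (st in c(1L, 2L, 5L)) {
    ph <- generate_phantom(phantom_spec(stage = st, seed = 21))
    expected <- if (st == 5L) 2L else 1L
    for (cid in c(2L, 3L, 4L, 5L)) {
      expect_equal(bf_components(ph$labels$data == cid), expected,
                   label = sprintf("stage %d class %d components", st, cid))
    }
  }
})

test_that("class mean intensities match the phantom intensity model", {
  spec <- phantom_spec(stage = 2, seed = 33)
  ph <- generate_phantom(spec)
  for (cls in names(sbf_classes)) {
    cid <- sbf_classes[[cls]]
    vals <- ph$raw$data[ph$labels$data == cid]
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - spec$intensity_means[[cls]]), 3 * se + 0.5,
              label = sprintf("mean intensity of %s", cls))
  }
})

test_that("cell waist narrows monotonically with stage (dumbbell pinch)", {
  waists <- vapply(1:5, function(st) {
    ph <- generate_phantom(phantom_spec(stage = st, seed = 12))
    u <- ph$meta$axis_u
    d <- dim(ph$labels$data)
    ctr <- (d + 1) / 2
    gc <- which(ph$labels$data > 0, arr.ind = TRUE)
    proj <- (gc[, 1] - ctr[1]) * u[1] + (gc[, 2] - ctr[2]) * u[2] +
      (gc[, 3] - ctr[3]) * u[3]
    sum(abs(proj) < 1)  # cross-section voxels in the central slab
  }, numeric(1))
  expect_true(all(diff(waists) <= 0))
})

test_that("phantoms whose cell exceeds the cube are rejected", {
  expect_error(generate_phantom(phantom_spec(stage = 5, cube_side = 32,
                                             cell_radius = 16, seed = 1)),
               "does not fit")
  expect_error(phantom_spec(stage = 1, organelle_fractions = c(
    plastid = 0.5, mitochondrion = 0.3, peroxisome = 0.1, nucleus = 0.2)),
    "sum")
  expect_error(phantom_spec(stage = 6), "stage")
})

test_that("scene instances respect the minimum gap", {
  sc <- generate_scene(scene_spec(n_cells = 3, min_gap = 4, seed = 71))
  expect_equal(sc$instances$n_instances, 3L)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_gte(bf_min_instance_distance(sc$instances$data, a, b), 4)
  }
})

test_that("single-cell scene yields instance values {0, 1}; empty scenes are rejected", {
  sc <- generate_scene(scene_spec(n_cells = 1, seed = 4))
  expect_identical(sort(unique(as.vector(sc$instances$data))), c(0L, 1L))
  expect_error(scene_spec(n_cells = 0), "n_cells")
})

test_that("impossible scene placement fails with an informative error", {
  expect_error(
    generate_scene(scene_spec(n_cells = 8, volume_shape = c(40L, 40L, 40L),
                              min_gap = 6, cell_radius = 10, seed = 1),
                   max_attempts = 50L),
    "placement budget|too large")
})

test_that("scene labels and instances agree on foreground voxels", {
  sc <- generate_scene(scene_spec(n_cells = 2, seed = 15))
  expect_identical(sc$labels$data > 0L, sc$instances$data > 0L)
  expect_identical(dim(sc$raw), dim(sc$labels))
})

test_that("anisotropic degradation keeps every factor-th slice and scales dz", {
  raw <- random_raw(c(12, 8, 8), seed = 6)
  deg <- degrade_anisotropic(raw, 2)
  expect_identical(dim(deg), c(6L, 8L, 8L))
  expect_equal(deg$spacing[["dz"]], 2)
  expect_identical(deg$data[3, , ], raw$data[5, , ])  # slice k -> 1 + 2(k-1)
  expect_error(degrade_anisotropic(raw, 1), "factor")
  expect_error(degrade_anisotropic(raw, 5), "divisible")
})
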