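make_prob_volume <- function(arr4, axis = "z") {
  structure(list(data = arr4, axis = axis, n_classes = dim(arr4)[4],
                 spacing = voxel_spacing(1, 1, 1)),
            class = "prob_volume")
}

random_prob4 <- function(d, seed) {
  withr::with_seed(seed, {
    a <- array(runif(prod(d)), d)
  })
  s <- apply(a, 1:3, sum)
  a / array(rep(s, d[4]), d)
}

test_that("directional inference reassembles probabilities into the common frame", {
  net <- micro_network(n_classes = 6, side = 16, base = 2, depth = 2)
  ph <- generate_phantom(phantom_spec(stage = 1, cube_side = 16,
                                      cell_radius = 5,
                                      organelle_fractions = c(
                                        plastid = 0.05, mitochondrion = 0,
                                        peroxisome = 0, nucleus = 0),
                                      seed = 3))
  v <- normalize_volume(ph$raw)
  pvs <- lapply(c("z", "y", "x"), function(a) infer_direction(net, v, a))
  for (pv in pvs) {
    expect_equal(dim(pv$data), c(16, 16, 16, 6))
    sums <- apply(pv$data, 1:3, sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
  # voxel bookkeeping: probabilities at a voxel along y/x must equal the
  # prediction of the section containing that voxel
  py <- pvs[[2]]
  sec <- predict_slices(net, reslice(v, "y"))[[5]]
  expect_equal(py$data[3, 5, 7, ], sec[3, 7, ])
  px <- pvs[[3]]
  sec <- predict_slices(net, reslice(v, "x"))[[7]]
  expect_equal(px$data[3, 5, 7, ], sec[3, 5, ])
})

test_that("fusing three identical volumes reduces to the per-voxel argmax", {
  p <- random_prob4(c(4, 4, 4, 6), seed = 1)
  fused <- fuse_directions(make_prob_volume(p, "z"), make_prob_volume(p, "y"),
                           make_prob_volume(p, "x"))
  am <- apply(p, 1:3, which.max) - 1L
  expect_identical(fused$data, array(as.integer(am), c(4, 4, 4)))
})

test_that("fusion picks the class with the single largest probability", {
  # one voxel, hand-built: dir-z favours class 2 at 0.9, the others class 3
  mk <- function(probs) make_prob_volume(array(probs, c(1, 1, 1, 6)))
  pz <- mk(c(0.02, 0.02, 0.9, 0.02, 0.02, 0.02))
  py <- mk(c(0.1, 0.1, 0.1, 0.6, 0.05, 0.05))
  px <- mk(c(0.06, 0.06, 0.06, 0.7, 0.06, 0.06))
  expect_equal(as.vector(fuse_directions(pz, py, px)$data), 2L)
})

test_that("fusion matches the brute-force 18-candidate oracle on random volumes", {
  for (seed in 1:4) {
    pz <- random_prob4(c(3, 4, 5, 6), seed = 10 * seed + 1)
    py <- random_prob4(c(3, 4, 5, 6), seed = 10 * seed + 2)
    px <- random_prob4(c(3, 4, 5, 6), seed = 10 * seed + 3)
    fused <- fuse_directions(make_prob_volume(pz), make_prob_volume(py),
                             make_prob_volume(px))
    expect_identical(fused$data, bf_fuse(pz, py, px))
  }
})

test_that("exact fusion ties resolve to the lowest class index", {
  mk <- function(probs) make_prob_volume(array(probs, c(1, 1, 1, 6)))
  # 0.5 for class 1 along z, 0.5 for class 4 along y
  pz <- mk(c(0.1, 0.5, 0.1, 0.1, 0.1, 0.1))
  py <- mk(c(0.1, 0.1, 0.1, 0.1, 0.5, 0.1))
  px <- mk(rep(1 / 6, 6))
  expect_equal(as.vector(fuse_directions(pz, py, px)$data), 1L)
  # reversed axis order: the lower class still wins regardless of direction
  expect_equal(as.vector(fuse_directions(py, pz, px)$data), 1L)
  expect_error(fuse_directions(pz, py,
                               make_prob_volume(random_prob4(c(2, 1, 1, 6), 1))),
               "mismatch")
})

test_that("fused output is a complete label volume over the six classes", {
  pz <- random_prob4(c(5, 5, 5, 6), seed = 31)
  py <- random_prob4(c(5, 5, 5, 6), seed = 32)
  px <- random_prob4(c(5, 5, 5, 6), seed = 33)
  fused <- fuse_directions(make_prob_volume(pz), make_prob_volume(py),
                           make_prob_volume(px))
  expect_s3_class(fused, "sbf_labels")
  expect_true(all(fused$data %in% 0:5))
  expect_true(is.numeric(attr(fused, "disagreement_fraction")))
})

test_that("mode filter removes speckle and leaves constants unchanged", {
  flat <- label_volume(array(1L, c(5, 5, 5)))
  expect_identical(denoise_labels(flat, 1)$data, flat$data)
  speck <- array(1L, c(5, 5, 5))
  speck[3, 3, 3] <- 4L
  out <- denoise_labels(label_volume(speck), 1)
  expect_equal(out$data[3, 3, 3], 1L)
  expect_error(denoise_labels(flat, 0), "radius")
})

test_that("mode filter matches the brute-force neighbourhood counting oracle", {
  withr::with_seed(9, {
    for (rep in 1:3) {
      lab <- array(sample(0:5, 6^3, TRUE, prob = c(0.5, 0.3, 0.05, 0.05, 0.05, 0.05)),
                   c(6, 6, 6))
      out <- denoise_labels(label_volume(lab), 1)
      expect_identical(out$data, bf_mode_filter(lab, 1L))
    }
  })
  # including a two-class checkerboard
  g <- expand.grid(z = 1:6, y = 1:6, x = 1:6)
  cb <- array(as.integer((g$z + g$y + g$x) %% 2), c(6, 6, 6))
  expect_identical(denoise_labels(label_volume(cb), 1)$data,
                   bf_mode_filter(cb, 1L))
})
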