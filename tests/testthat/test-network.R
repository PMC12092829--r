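# Architecture, forward contract, and gradient correctness.

# the published full-scale layer table: kernel (KxKxOxI) and output (OxWxH)
full_scale_rows <- data.frame(
  layer = c(sprintf("conv%d", 1:10), sprintf("deconv%d", 1:8), "final"),
  channels = c(64, 64, 128, 128, 256, 256, 512, 512, 1024, 1024,
               512, 512, 256, 256, 128, 128, 64, 64, 6),
  height = c(256, 256, 128, 128, 64, 64, 32, 32, 16, 16,
             32, 32, 64, 64, 128, 128, 256, 256, 256),
  width = c(256, 256, 128, 128, 64, 64, 32, 32, 16, 16,
            32, 32, 64, 64, 128, 128, 256, 256, 256),
  in_channels = c(1, 64, 64, 128, 128, 256, 256, 512, 512, 1024,
                  1024, 512, 512, 256, 256, 128, 128, 64, 64),
  kernel = c(rep(3, 18), 1))

test_that("layer shape schedule matches the full-scale architecture table", {
  shapes <- network_shapes(network_config())
  expect_equal(shapes$layer, full_scale_rows$layer)
  expect_equal(shapes$channels, full_scale_rows$channels)
  expect_equal(shapes$height, full_scale_rows$height)
  expect_equal(shapes$width, full_scale_rows$width)
})

test_that("scaled-down configs follow the channel-doubling arithmetic", {
  shapes <- network_shapes(network_config(base_channels = 8, input_side = 64,
                                          depth = 5))
  deepest <- shapes[shapes$layer == "conv10", ]
  expect_equal(unlist(deepest[, c("channels", "height", "width")]),
               c(channels = 128, height = 4, width = 4))
  expect_error(network_config(input_side = 100, depth = 5), "divisible")
})

test_that("forward intermediates agree with the declared shape table", {
  cfg <- network_config(n_classes = 6, input_side = 16, base_channels = 2,
                        depth = 3)
  net <- build_network(cfg, seed = 1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  fw <- sbfseg:::forward_network(net, x, training = FALSE, want_cache = TRUE)
  shapes <- network_shapes(cfg)
  d <- cfg$depth
  for (s in seq_len(d)) {
    got <- dim(fw$cache$enc[[paste0("s", s)]]$a2)
    row <- shapes[shapes$layer == sprintf("conv%d", 2 * s), ]
    expect_equal(got[1:3], c(row$height, row$width, row$channels))
  }
  for (s in seq_len(d - 1)) {
    got <- dim(fw$cache$dec[[paste0("s", s)]]$a2)
    row <- shapes[shapes$layer == sprintf("deconv%d", 2 * (d - s)), ]
    expect_equal(got[1:3], c(row$height, row$width, row$channels))
  }
  expect_equal(dim(fw$probs), c(16, 16, 6, 2))
})

test_that("softmax output is a per-pixel probability distribution", {
  net <- micro_network(n_classes = 6, side = 16, base = 2, depth = 2)
  sl <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  pr <- predict_slices(net, sl)
  expect_length(pr, 2)
  for (p in pr) {
    expect_equal(dim(p), c(16, 16, 6))
    sums <- apply(p, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_gte(min(p), 0)
  }
})

test_that("inference is pure: identical sections give identical outputs", {
  net <- micro_network(n_classes = 6, side = 16, base = 2, depth = 2)
  s <- matrix(runif(256), 16, 16)
  pr <- predict_slices(net, list(s, s))
  expect_identical(pr[[1]], pr[[2]])
  expect_length(predict_slices(net, list()), 0)
  expect_error(predict_slices(net, list(matrix(0, 8, 8))), "input side")
})

test_that("analytic gradients match central finite differences", {
  # every variant of the architecture: attention / plain, BN / none,
  # transposed / nearest upsampling
  variants <- list(
    list(att = TRUE, bn = TRUE, up = "transposed"),
    list(att = TRUE, bn = FALSE, up = "transposed"),
    list(att = FALSE, bn = TRUE, up = "nearest"))
  for (vt in variants) {
    net <- micro_network(n_classes = 4, side = 8, base = 2, depth = 2,
                         attention = vt$att, batch_norm = vt$bn,
                         upsample = vt$up)
    withr::with_seed(7, {
      x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
      lab <- array(sample(0:3, 8 * 8 * 2, TRUE), c(8, 8, 2))
    })
    t4 <- array(0, c(8, 8, 4, 2))
    for (c in 1:4) t4[, , c, ] <- (lab == c - 1)
    loss_of <- function(n) {
      fw <- sbfseg:::forward_network(n, x, training = TRUE)
      sbfseg:::tversky_batch(fw$probs, t4, 0.3, 0.7, 1e-6)$loss
    }
    fw <- sbfseg:::forward_network(net, x, training = TRUE, want_cache = TRUE)
    tb <- sbfseg:::tversky_batch(fw$probs, t4, 0.3, 0.7, 1e-6)
    grads <- sbfseg:::backward_network(net, fw$cache,
                                       sbfseg:::softmax4_bw(fw$probs, tb$dP))
    eps <- 1e-6
    withr::with_seed(17, {
      for (pp in sbfseg:::param_paths(net)) {
        arr <- net$params[[pp$path]]
        g <- grads[[pp$path]]
        expect_false(is.null(g),
                     label = paste("gradient for", paste(pp$path, collapse = "/")))
        for (i in sample(length(arr), min(2, length(arr)))) {
          n1 <- net; n1$params[[pp$path]][i] <- arr[i] + eps
          n2 <- net; n2$params[[pp$path]][i] <- arr[i] - eps
          num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
          expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4,
                    label = sprintf("grad %s[%d] (%s)",
                                    paste(pp$path, collapse = "/"), i,
                                    paste(unlist(vt), collapse = "/")))
        }
      }
    })
  }
})

test_that("parameter count scales as expected and is reported", {
  tiny <- build_network(network_config(input_side = 32, base_channels = 4,
                                       depth = 3), seed = 1)
  n <- count_parameters(tiny)
  expect_gt(n, 1000)
  bigger <- build_network(network_config(input_side = 32, base_channels = 8,
                                         depth = 3), seed = 1)
  # channel doubling roughly quadruples convolution parameters
  expect_gt(count_parameters(bigger) / n, 3)
})

test_that("checkpoints round trip through disk", {
  net <- micro_network()
  p <- withr::local_tempfile(fileext = ".rds")
  save_network(net, p)
  back <- load_network(p)
  expect_identical(back$params, net$params)
  expect_identical(back$config, net$config)
})
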