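test_that("tversky loss is zero exactly on a perfect hard prediction", {
  withr::with_seed(1, {
    lab <- matrix(sample(0:5, 64, TRUE), 8, 8)
  })
  hard <- one_hot(lab, 6)
  expect_equal(tversky_loss(hard, lab), 0)
  expect_equal(tversky_loss(hard, hard), 0)
})

test_that("tversky with alpha = beta = 0.5 equals soft Dice loss", {
  withr::with_seed(2, {
    for (rep in 1:10) {
      logits <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
      pred <- exp(logits)
      pred <- pred / array(rep(apply(pred, c(1, 2), sum), 6), dim(pred))
      lab <- matrix(sample(0:5, 64, TRUE), 8, 8)
      truth <- one_hot(lab, 6)
      expect_lt(abs(tversky_loss(pred, truth, 0.5, 0.5) -
                      bf_dice_loss(pred, truth)), 1e-12)
    }
  })
})

test_that("tversky on a one-pixel section matches the scalar hand calculation", {
  # truth class 2, uniform prediction 1/6, alpha 0.3, beta 0.7
  pred <- array(1 / 6, c(1, 1, 6))
  lab <- matrix(2L, 1, 1)
  s <- 1e-6
  ti <- numeric(6)
  for (c in 0:5) {
    tp <- if (c == 2) 1 / 6 else 0
    fp <- if (c == 2) 0 else 1 / 6
    fn <- if (c == 2) 5 / 6 else 0
    ti[c + 1] <- (tp + s) / (tp + 0.3 * fp + 0.7 * fn + s)
  }
  expect_equal(tversky_loss(pred, lab, 0.3, 0.7, smooth = s),
               mean(1 - ti), tolerance = 1e-12)
})

test_that("tversky loss validates weights and shapes", {
  pred <- array(1 / 6, c(2, 2, 6))
  lab <- matrix(0L, 2, 2)
  expect_error(tversky_loss(pred, lab, alpha = 0), "alpha")
  expect_error(tversky_loss(pred, lab, beta = 1.5), "beta")
  expect_error(tversky_loss(pred, one_hot(matrix(0L, 3, 3), 6)), "shapes")
})

test_that("loss is invariant to a consistent class relabelling", {
  withr::with_seed(3, {
    pred <- array(runif(8 * 8 * 6), c(8, 8, 6))
    pred <- pred / array(rep(apply(pred, c(1, 2), sum), 6), dim(pred))
    lab <- matrix(sample(0:5, 64, TRUE), 8, 8)
  })
  perm <- sample(1:6)
  pred2 <- pred[, , perm]
  lab2 <- matrix(match(lab + 1L, perm) - 1L, 8, 8)
  expect_equal(tversky_loss(pred, lab), tversky_loss(pred2, lab2),
               tolerance = 1e-12)
  # and to a permutation of pixels applied to both
  pix <- sample(64)
  pred3 <- array(apply(pred, 3, function(m) m[pix]), dim(pred))
  lab3 <- matrix(lab[pix], 8, 8)
  expect_equal(tversky_loss(pred, lab), tversky_loss(pred3, lab3),
               tolerance = 1e-12)
})

test_that("the learning-rate schedule decays by the configured factor each epoch", {
  cfg <- train_config(base_lr = 1e-5, lr_decay_per_epoch = 0.95, epochs = 5)
  expect_equal(lr_schedule(cfg), 1e-5 * 0.95^(0:4))
  cfg2 <- train_config(epochs = 2)
  expect_equal(lr_schedule(cfg2), c(1e-5, 9.5e-6))
  expect_true(all(diff(lr_schedule(cfg)) < 0))
})

test_that("training on one repeated section drives the loss below its start", {
  ph <- memo("train_phantom", generate_phantom(phantom_spec(
    stage = 2, cube_side = 32, organelle_fractions = small_fractions,
    seed = 44)))
  img <- normalize_volume(ph$raw)$data[16, , ]
  lab <- ph$labels$data[16, , ]
  sections <- rep(list(list(image = img, label = lab)), 8)
  net <- build_network(network_config(input_side = 32, base_channels = 4,
                                      depth = 3), seed = 2)
  fit <- train_network(net, sections,
                       config = train_config(base_lr = 2e-3, epochs = 6,
                                             batch_size = 8, seed = 2))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("training is deterministic given its seeds", {
  ph <- memo("train_phantom", generate_phantom(phantom_spec(
    stage = 2, cube_side = 32, organelle_fractions = small_fractions,
    seed = 44)))
  img <- normalize_volume(ph$raw)$data[10, , ]
  lab <- ph$labels$data[10, , ]
  sections <- rep(list(list(image = img, label = lab)), 4)
  run <- function() {
    net <- build_network(network_config(input_side = 32, base_channels = 2,
                                        depth = 2), seed = 5)
    train_network(net, sections,
                  config = train_config(base_lr = 1e-3, epochs = 2,
                                        batch_size = 4, seed = 5))$history
  }
  expect_equal(run()$train_loss, run()$train_loss, tolerance = 1e-12)
})

test_that("a tiny network overfits a handful of phantom sections", {
  ph <- memo("train_phantom", generate_phantom(phantom_spec(
    stage = 2, cube_side = 32, organelle_fractions = small_fractions,
    seed = 44)))
  v <- normalize_volume(ph$raw)
  sections <- lapply(c(12, 16, 20, 24), function(i)
    list(image = v$data[i, , ], label = ph$labels$data[i, , ]))
  net <- build_network(network_config(input_side = 32, base_channels = 8,
                                      depth = 3), seed = 7)
  fit <- train_network(net, sections,
                       config = train_config(base_lr = 1e-2,
                                             lr_decay_per_epoch = 1,
                                             epochs = 400, batch_size = 4,
                                             seed = 7))
  expect_lt(min(fit$history$train_loss), 0.05)
})

test_that("training rejects malformed inputs", {
  net <- build_network(network_config(input_side = 32, base_channels = 2,
                                      depth = 2), seed = 1)
  expect_error(train_network(net, list()), "empty")
  bad <- list(list(image = matrix(0, 16, 16), label = matrix(0L, 16, 16)))
  expect_error(train_network(net, bad), "input side")
})
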