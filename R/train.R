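# Training: Tversky loss on softmax outputs, AdamW with a per-epoch
# exponentially decaying learning rate.

#' Training configuration
#'
#' Defaults follow the acquisition-scale schedule: AdamW from a base
#' learning rate of 1e-5 decaying by a factor of 0.95 each epoch, 5 epochs.
#' Desk-scale experiments on small synthetic volumes use far fewer optimizer
#' steps, where a correspondingly larger base rate is appropriate (see the
#' package vignette).
#'
#' @param base_lr Base learning rate (epoch 1).
#' @param lr_decay_per_epoch Multiplicative decay applied each epoch; the
#'   learning rate of epoch e is `base_lr * lr_decay_per_epoch^(e - 1)`.
#' @param epochs Number of passes over the training sections.
#' @param batch_size Sections per optimizer step.
#' @param tversky_alpha,tversky_beta False-positive and false-negative
#'   weights of the Tversky loss, each in (0, 1].  The defaults 0.3/0.7
#'   weight false negatives more heavily, which favours recall of small
#'   organelles.
#' @param weight_decay AdamW decoupled weight decay on convolution kernels.
#' @param seed RNG seed controlling data order (weight initialization is
#'   seeded separately in [build_network()]).
#' @param val_max_sections Cap on validation sections scored per epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(base_lr = 1e-5, lr_decay_per_epoch = 0.95,
                         epochs = 5L, batch_size = 8L,
                         tversky_alpha = 0.3, tversky_beta = 0.7,
                         weight_decay = 0.01, seed = 1L,
                         val_max_sections = 32L) {
  if (base_lr <= 0) stop("base_lr must be positive")
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch > 1)
    stop("lr_decay_per_epoch must be in (0, 1]")
  check_tversky_weights(tversky_alpha, tversky_beta)
  structure(list(base_lr = base_lr, lr_decay_per_epoch = lr_decay_per_epoch,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 val_max_sections = as.integer(val_max_sections)),
            class = "train_config")
}

check_tversky_weights <- function(alpha, beta) {
  if (alpha <= 0 || alpha > 1 || beta <= 0 || beta > 1)
    stop("tversky alpha and beta must lie in (0, 1]")
  invisible(TRUE)
}

#' Learning-rate schedule
#'
#' @param config A [train_config()].
#' @return Numeric vector of per-epoch learning rates,
#'   `base_lr * decay^(e-1)`.
#' @export
lr_schedule <- function(config) {
  config$base_lr * config$lr_decay_per_epoch^(seq_len(config$epochs) - 1L)
}

#' One-hot encoding of a label section
#'
#' @param label Integer matrix of class codes 0..(n_classes-1).
#' @param n_classes Number of classes.
#' @return `(H, W, n_classes)` array of 0/1 indicators.
#' @export
one_hot <- function(label, n_classes = 6L) {
  d <- dim(label)
  out <- array(0, c(d[1], d[2], n_classes))
  for (c in seq_len(n_classes)) out[, , c] <- (label == c - 1L)
  out
}

#' Tversky loss of a predicted section
#'
#' Per-class Tversky index on soft predictions,
#' `TI_c = (TP_c + s) / (TP_c + alpha FP_c + beta FN_c + s)`, with
#' `TP_c = sum(p_c t_c)`, `FP_c = sum(p_c (1 - t_c))`,
#' `FN_c = sum((1 - p_c) t_c)` and smoothing `s`; the loss is the mean over
#' classes of `1 - TI_c`.  It is zero exactly when the prediction equals the
#' one-hot truth.  With `alpha = beta = 0.5` the index reduces algebraically
#' to the soft Dice coefficient.
#'
#' @param pred `(H, W, n_classes)` probability array (softmax output).
#' @param truth One-hot `(H, W, n_classes)` array, or an integer `(H, W)`
#'   matrix of class codes.
#' @param alpha,beta False-positive / false-negative weights in (0, 1].
#' @param smooth Smoothing constant guarding empty classes (a class absent
#'   from both prediction and truth scores TI = 1).
#' @return Nonnegative scalar loss.
#' @export
tversky_loss <- function(pred, truth, alpha = 0.3, beta = 0.7,
                         smooth = 1e-6) {
  check_tversky_weights(alpha, beta)
  if (is.matrix(truth)) truth <- one_hot(truth, dim(pred)[3])
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  d <- dim(pred)
  p4 <- array(pred, c(d, 1L))
  t4 <- array(truth, c(d, 1L))
  tversky_batch(p4, t4, alpha, beta, smooth)$loss
}

# Batched Tversky loss and its gradient wrt the probabilities.
# P, truth: (H, W, C, N).  Loss is the mean over samples and classes of 1 - TI.
tversky_batch <- function(P, truth, alpha, beta, smooth) {
  d <- dim(P)
  hw <- d[1] * d[2]
  cn <- d[3] * d[4]
  Pm <- matrix(P, nrow = hw)
  Tm <- matrix(truth, nrow = hw)
  TP <- .colSums(Pm * Tm, hw, cn)
  sumP <- .colSums(Pm, hw, cn)
  sumT <- .colSums(Tm, hw, cn)
  FP <- sumP - TP
  FN <- sumT - TP
  den <- TP + alpha * FP + beta * FN
  TI <- (TP + smooth) / (den + smooth)
  loss <- mean(1 - TI)
  # dTI/dp = [t (den+s) - (TP+s) (alpha + t (1 - alpha - beta))] / (den+s)^2
  dens <- den + smooth
  c2 <- rep((TP + smooth) / dens^2, each = hw)
  c3 <- rep(1 / dens, each = hw)
  dP_m <- -(Tm * c3 - c2 * (alpha + Tm * (1 - alpha - beta))) / cn
  dP <- array(dP_m, d)
  list(loss = loss, dP = dP, TI = matrix(TI, d[3], d[4]))
}

# One AdamW step over every trainable array.  state carries first/second
# moments and the global step counter.
adamw_step <- function(params, grads, state, lr, weight_decay, paths,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(paths)) {
    pth <- paths[[k]]$path
    g <- grads[[pth]]
    if (is.null(g)) next
    m <- beta1 * state$m[[k]] + (1 - beta1) * g
    v <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    state$m[[k]] <- m
    state$v[[k]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (paths[[k]]$decay && weight_decay > 0)
      upd <- upd + weight_decay * params[[pth]]
    params[[pth]] <- params[[pth]] - lr * upd
  }
  list(params = params, state = state)
}

#' Train the network
#'
#' Runs AdamW over the training sections for the configured number of
#' epochs, with the learning rate decaying by the configured factor each
#' epoch.  Fully seeded: weight initialization through the seed given to
#' [build_network()], data order through the training-config seed.
#'
#' @param network An `sbf_network` from [build_network()].
#' @param training List of section pairs `list(image, label)` (e.g. from
#'   [augment_training_set()]); images in \[0, 1\], labels integer class
#'   codes; all sized to the network input side.
#' @param validation Optional list of section pairs scored (forward only)
#'   after each epoch.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list with the trained `network` (including attached `history`)
#'   and the per-epoch `history` data.frame (epoch, lr, train and validation
#'   loss).
#' @export
train_network <- function(network, training, validation = NULL,
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(network, "sbf_network"), inherits(config, "train_config"))
  if (!length(training)) stop("training set is empty")
  side <- network$config$input_side
  nc <- network$config$n_classes
  for (pr in training)
    if (!identical(dim(pr$image), c(side, side)))
      stop(sprintf("training section size (%s) does not match network input side %d",
                   paste(dim(pr$image), collapse = "x"), side))
  withr::local_seed(config$seed)

  paths <- param_paths(network)
  state <- list(
    m = lapply(paths, function(p) array(0, dim(network$params[[p$path]]) %||%
                                          length(network$params[[p$path]]))),
    v = lapply(paths, function(p) array(0, dim(network$params[[p$path]]) %||%
                                          length(network$params[[p$path]]))),
    t = 0L)

  lrs <- lr_schedule(config)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_loss = numeric(0))
  n <- length(training)
  for (epoch in seq_len(config$epochs)) {
    lr <- lrs[epoch]
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      B <- length(bi)
      x <- array(0, c(side, side, 1L, B))
      t4 <- array(0, c(side, side, nc, B))
      for (k in seq_len(B)) {
        x[, , 1L, k] <- training[[bi[k]]]$image
        lab <- training[[bi[k]]]$label
        for (c in seq_len(nc)) t4[, , c, k] <- (lab == c - 1L)
      }
      fw <- forward_network(network, x, training = TRUE, want_cache = TRUE)
      network$stats <- fw$stats
      tb <- tversky_batch(fw$probs, t4, config$tversky_alpha,
                          config$tversky_beta, 1e-6)
      dZ <- softmax4_bw(fw$probs, tb$dP)
      grads <- backward_network(network, fw$cache, dZ)
      up <- adamw_step(network$params, grads, state, lr,
                       config$weight_decay, paths)
      network$params <- up$params
      state <- up$state
      ep_loss <- ep_loss + tb$loss * B
    }
    ep_loss <- ep_loss / n
    vl <- NA_real_
    if (!is.null(validation) && length(validation)) {
      vidx <- head(seq_along(validation), config$val_max_sections)
      vloss <- 0
      for (ii in split(vidx, ceiling(seq_along(vidx) / config$batch_size))) {
        B <- length(ii)
        x <- array(0, c(side, side, 1L, B))
        t4 <- array(0, c(side, side, nc, B))
        for (k in seq_len(B)) {
          x[, , 1L, k] <- validation[[ii[k]]]$image
          lab <- validation[[ii[k]]]$label
          for (c in seq_len(nc)) t4[, , c, k] <- (lab == c - 1L)
        }
        pb <- forward_network(network, x, training = FALSE)$probs
        vloss <- vloss + tversky_batch(pb, t4, config$tversky_alpha,
                                       config$tversky_beta, 1e-6)$loss * B
      }
      vl <- vloss / length(vidx)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d  lr %.3g  train %.4f  val %s",
                      epoch, lr, ep_loss,
                      if (is.na(vl)) "-" else sprintf("%.4f", vl)))
  }
  network$history <- hist
  network$train_config <- config
  list(network = network, history = hist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
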