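# Scanning attention U-Net.
#
# A 2D encoder-decoder applied section-by-section through the 3D volume
# ("scanning"): paired 3x3 same-padding convolutions with batch
# normalization and ReLU at every stage, 2x2 max pooling between encoder
# stages, channel count doubling per stage, transposed-convolution (or
# nearest+conv) upsampling in the decoder, additive attention gates on the
# skip connections, and a final 1x1 convolution to the six classes with a
# per-pixel softmax (no batch normalization on the head).
#
# No deep-learning framework is involved: forward and backward passes are
# written out layer by layer in R on top of GEMM-based C++ convolution
# kernels, which keeps the arithmetic transparent and the package
# self-contained.

#' Network configuration
#'
#' @param n_classes Number of output classes (6: the organelle taxonomy).
#' @param input_side Side of the square input sections in pixels
#'   (256 at acquisition scale).  Must be divisible by `2^(depth - 1)`.
#' @param base_channels Channels of the first encoder stage (64 at
#'   acquisition scale); doubled at each deeper stage.
#' @param depth Number of encoder stages including the bottleneck (5 at
#'   acquisition scale, giving channel levels 64, 128, 256, 512, 1024).
#' @param attention Use additive attention gates on the decoder skip
#'   connections.
#' @param batch_norm Batch-normalize every convolution except the final
#'   1x1 head.
#' @param upsample `"transposed"` (2x2 transposed convolution, the default)
#'   or `"nearest"` (nearest-neighbour upsampling followed by a 3x3
#'   convolution).
#' @return A `network_config` object.
#' @export
network_config <- function(n_classes = 6L, input_side = 256L,
                           base_channels = 64L, depth = 5L,
                           attention = TRUE, batch_norm = TRUE,
                           upsample = c("transposed", "nearest")) {
  upsample <- match.arg(upsample)
  input_side <- as.integer(input_side)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  if (depth < 2L) stop("depth must be >= 2")
  if (input_side %% 2L^(depth - 1L) != 0L)
    stop(sprintf("input_side %d not divisible by 2^(depth-1) = %d",
                 input_side, 2L^(depth - 1L)))
  structure(list(n_classes = as.integer(n_classes), input_side = input_side,
                 base_channels = base_channels, depth = depth,
                 attention = attention, batch_norm = batch_norm,
                 upsample = upsample),
            class = "network_config")
}

stage_channels <- function(config) config$base_channels * 2L^(seq_len(config$depth) - 1L)

#' Per-layer output shapes of the network
#'
#' Computes the (channels, height, width) of every convolution output by the
#' stage arithmetic alone (channel doubling, 2x spatial halving), without
#' allocating weights.  Encoder rows are named `conv1..conv2d`, decoder rows
#' `deconv1..deconv2(d-1)`, and the softmax head `final`.
#'
#' @param config A [network_config()].
#' @return A data.frame with columns `layer`, `channels`, `height`, `width`.
#' @export
network_shapes <- function(config) {
  ch <- stage_channels(config)
  d <- config$depth
  side <- config$input_side
  rows <- list()
  for (s in seq_len(d)) {
    res <- side / 2L^(s - 1L)
    for (k in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("conv%d", 2L * (s - 1L) + k),
        channels = ch[s], height = res, width = res)
  }
  for (i in seq_len(d - 1L)) {
    s <- d - i  # decoder stage
    res <- side / 2L^(s - 1L)
    for (k in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("deconv%d", 2L * (i - 1L) + k),
        channels = ch[s], height = res, width = res)
  }
  rows[[length(rows) + 1L]] <- data.frame(layer = "final",
                                          channels = config$n_classes,
                                          height = side, width = side)
  do.call(rbind, rows)
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)

new_conv <- function(K, cin, cout) {
  list(w = he_init(c(K, K, cin, cout), K * K * cin), b = numeric(cout))
}

#' Build a scanning attention U-Net
#'
#' Allocates and initializes all weights (He initialization for
#' convolutions, unit gain / zero shift for batch normalization) for the
#' architecture described by the configuration.
#'
#' @param config A [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return An `sbf_network`: configuration, parameter tree, and batch-norm
#'   running statistics.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  withr::local_seed(seed)
  ch <- stage_channels(config)
  d <- config$depth
  params <- list(enc = list(), up = list(), att = list(), dec = list())
  stats <- list(enc = list(), dec = list())

  bn_pair <- function(c) list(gamma = rep(1, c), beta = numeric(c))
  bn_stats <- function(c) list(mean = numeric(c), var = rep(1, c))

  bn_block <- function(c) {
    if (!config$batch_norm) return(NULL)
    out <- c(setNames(bn_pair(c), c("g1", "be1")),
             setNames(bn_pair(c), c("g2", "be2")))
    out
  }
  cin <- 1L
  for (s in seq_len(d)) {
    sn <- paste0("s", s)
    params$enc[[sn]] <- c(
      setNames(new_conv(3L, cin, ch[s]), c("w1", "b1")),
      setNames(new_conv(3L, ch[s], ch[s]), c("w2", "b2")),
      bn_block(ch[s]))
    stats$enc[[sn]] <- list(bn1 = bn_stats(ch[s]), bn2 = bn_stats(ch[s]))
    cin <- ch[s]
  }
  for (s in seq_len(d - 1L)) {
    sn <- paste0("s", s)
    if (config$upsample == "transposed") {
      params$up[[sn]] <- list(
        w = he_init(c(2L, 2L, ch[s + 1L], ch[s]), 4L * ch[s + 1L]),
        b = numeric(ch[s]))
    } else {
      params$up[[sn]] <- setNames(new_conv(3L, ch[s + 1L], ch[s]), c("w", "b"))
    }
    if (config$attention) {
      ca <- max(ch[s] %/% 2L, 1L)
      params$att[[sn]] <- list(
        wg = array(rnorm(ch[s] * ca, sd = sqrt(1 / ch[s])), c(1L, 1L, ch[s], ca)),
        wx = array(rnorm(ch[s] * ca, sd = sqrt(1 / ch[s])), c(1L, 1L, ch[s], ca)),
        bgx = numeric(ca),
        wpsi = array(rnorm(ca, sd = sqrt(1 / ca)), c(1L, 1L, ca, 1L)),
        bpsi = numeric(1L))
    }
    params$dec[[sn]] <- c(
      setNames(new_conv(3L, 2L * ch[s], ch[s]), c("w1", "b1")),
      setNames(new_conv(3L, ch[s], ch[s]), c("w2", "b2")),
      bn_block(ch[s]))
    stats$dec[[sn]] <- list(bn1 = bn_stats(ch[s]), bn2 = bn_stats(ch[s]))
  }
  params$final <- new_conv(1L, ch[1], config$n_classes)

  structure(list(config = config, params = params, stats = stats,
                 init_seed = as.integer(seed)),
            class = "sbf_network")
}

#' @export
print.sbf_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("scanning attention U-Net: depth %d, base %d channels, ",
                     "%dx%d input, %d classes%s%s\n  %s parameters\n"),
              cfg$depth, cfg$base_channels, cfg$input_side, cfg$input_side,
              cfg$n_classes,
              if (cfg$attention) ", attention gates" else "",
              if (cfg$batch_norm) ", batch norm" else "",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param network An `sbf_network`.
#' @return Integer total across all weight arrays.
#' @export
count_parameters <- function(network) {
  sum(vapply(param_paths(network),
             function(p) length(network$params[[p$path]]), numeric(1)))
}

# Enumerate trainable parameter arrays as character paths into net$params.
# AdamW weight decay applies only to convolution kernels (names starting
# with "w"), never to biases or batch-norm affine terms.
param_paths <- function(network) {
  out <- list()
  walk <- function(node, path) {
    for (nm in names(node)) {
      el <- node[[nm]]
      if (is.list(el)) walk(el, c(path, nm))
      else out[[length(out) + 1L]] <<- list(path = c(path, nm),
                                            decay = startsWith(nm, "w"))
    }
  }
  walk(network$params, character(0))
  out
}

# --- primitive layers -------------------------------------------------------

conv_fw <- function(x, w, b) {
  K <- dim(w)[1]
  .conv2d_forward(x, matrix(w, K * K * dim(w)[3], dim(w)[4]), b, K)
}

conv_bw <- function(x, w, dy) {
  K <- dim(w)[1]
  r <- .conv2d_backward(x, matrix(w, K * K * dim(w)[3], dim(w)[4]), dy, K)
  r$dw <- array(r$dw, dim(w))
  r
}

bcast_channel <- function(v, d) {
  # per-channel vector v broadcast over an (H,W,C,N) geometry
  array(rep(rep(v, times = d[4]), each = d[1] * d[2]), d)
}

channel_stat_sums <- function(x, d) {
  # per-channel sums over pixels and batch
  m <- matrix(x, nrow = d[1] * d[2])
  rowSums(matrix(.colSums(m, d[1] * d[2], d[3] * d[4]), d[3]))
}

bn_fw <- function(x, gamma, beta, st, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- prod(d[c(1, 2, 4)])
  if (training) {
    mu <- channel_stat_sums(x, d) / m
    ex2 <- channel_stat_sums(x * x, d) / m
    va <- pmax(ex2 - mu^2, 0)
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va
  } else {
    mu <- st$mean
    va <- st$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x - bcast_channel(mu, d)) * bcast_channel(invstd, d)
  y <- xhat * bcast_channel(gamma, d) + bcast_channel(beta, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       stats = st)
}

bn_bw <- function(dy, cache) {
  d <- dim(dy)
  m <- prod(d[c(1, 2, 4)])
  s1 <- channel_stat_sums(dy, d)
  s2 <- channel_stat_sums(dy * cache$xhat, d)
  gi <- cache$gamma * cache$invstd / m
  dx <- bcast_channel(gi, d) *
    (m * dy - bcast_channel(s1, d) - cache$xhat * bcast_channel(s2, d))
  list(dx = dx, dgamma = s2, dbeta = s1)
}

channel_sum <- function(x) {
  d <- dim(x)
  acc <- x[, , 1, , drop = FALSE]
  if (d[3] > 1)
    for (c in 2:d[3]) acc <- acc + x[, , c, , drop = FALSE]
  array(acc, c(d[1], d[2], 1L, d[4]))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

nn_upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

nn_upsample2_bw <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], by = 2L); ie <- io + 1L
  jo <- seq(1L, d[2], by = 2L); je <- jo + 1L
  dy[io, jo, , , drop = FALSE] + dy[ie, jo, , , drop = FALSE] +
    dy[io, je, , , drop = FALSE] + dy[ie, je, , , drop = FALSE]
}

softmax4 <- function(z) {
  d <- dim(z)
  mx <- z[, , 1, ]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, z[, , c, ])
  p <- z
  for (c in seq_len(d[3])) p[, , c, ] <- exp(z[, , c, ] - mx)
  s <- p[, , 1, ]
  for (c in seq_len(d[3])[-1]) s <- s + p[, , c, ]
  for (c in seq_len(d[3])) p[, , c, ] <- p[, , c, ] / s
  p
}

softmax4_bw <- function(p, dp) {
  # gradient through per-pixel softmax: dz = p * (dp - sum_c dp*p)
  d <- dim(p)
  s <- (dp * p)[, , 1, ]
  for (c in seq_len(d[3])[-1]) s <- s + (dp * p)[, , c, ]
  dz <- dp
  for (c in seq_len(d[3])) dz[, , c, ] <- p[, , c, ] * (dp[, , c, ] - s)
  dz
}

# --- forward / backward -----------------------------------------------------

# Forward pass over a batch of sections x (H, W, 1, N).  Returns class
# probabilities (H, W, n_classes, N); with want_cache, every intermediate
# needed by backward_network; in training mode, updated batch-norm running
# statistics.
forward_network <- function(network, x, training = FALSE, want_cache = FALSE) {
  cfg <- network$config
  p <- network$params
  st <- network$stats
  d <- cfg$depth
  cache <- list(enc = list(), dec = list())

  enc_out <- vector("list", d)
  x_cur <- x
  for (s in seq_len(d)) {
    sn <- paste0("s", s)
    e <- list(xin = x_cur)
    pe <- p$enc[[sn]]
    z1 <- conv_fw(x_cur, pe$w1, pe$b1)
    if (cfg$batch_norm) {
      r <- bn_fw(z1, pe$g1, pe$be1, st$enc[[sn]]$bn1, training)
      e$z1 <- z1; e$bn1 <- r$cache; st$enc[[sn]]$bn1 <- r$stats
      a1 <- r$y
    } else a1 <- z1
    e$a1 <- a1
    r1 <- pmax(a1, 0)
    e$r1 <- r1
    z2 <- conv_fw(r1, pe$w2, pe$b2)
    if (cfg$batch_norm) {
      r <- bn_fw(z2, pe$g2, pe$be2, st$enc[[sn]]$bn2, training)
      e$z2 <- z2; e$bn2 <- r$cache; st$enc[[sn]]$bn2 <- r$stats
      a2 <- r$y
    } else a2 <- z2
    e$a2 <- a2
    r2 <- pmax(a2, 0)
    enc_out[[s]] <- r2
    if (s < d) {
      pl <- .maxpool2_forward(r2)
      x_cur <- pl$y
      e$pool_idx <- pl$idx
    }
    cache$enc[[sn]] <- e
  }

  x_cur <- enc_out[[d]]
  for (s in rev(seq_len(d - 1L))) {
    sn <- paste0("s", s)
    dc <- list(up_in = x_cur)
    pu <- p$up[[sn]]
    if (cfg$upsample == "transposed") {
      g <- .upconv2_forward(x_cur, pu$w, pu$b)
    } else {
      dc$up_nn <- nn_upsample2(x_cur)
      g <- conv_fw(dc$up_nn, pu$w, pu$b)
    }
    dc$g <- g
    skip <- enc_out[[s]]
    if (cfg$attention) {
      pa <- p$att[[sn]]
      a <- conv_fw(g, pa$wg, numeric(dim(pa$wg)[4])) +
        conv_fw(skip, pa$wx, pa$bgx)
      f <- pmax(a, 0)
      psil <- conv_fw(f, pa$wpsi, pa$bpsi)
      psi <- 1 / (1 + exp(-psil))
      skip_g <- skip * psi[, , rep(1L, dim(skip)[3]), , drop = FALSE]
      dc$att <- list(a = a, f = f, psi = psi, skip = skip)
    } else skip_g <- skip
    cat_in <- concat_channels(g, skip_g)
    dc$cat <- cat_in
    pd <- p$dec[[sn]]
    z1 <- conv_fw(cat_in, pd$w1, pd$b1)
    if (cfg$batch_norm) {
      r <- bn_fw(z1, pd$g1, pd$be1, st$dec[[sn]]$bn1, training)
      dc$bn1 <- r$cache; st$dec[[sn]]$bn1 <- r$stats
      a1 <- r$y
    } else a1 <- z1
    dc$a1 <- a1
    r1 <- pmax(a1, 0)
    dc$r1 <- r1
    z2 <- conv_fw(r1, pd$w2, pd$b2)
    if (cfg$batch_norm) {
      r <- bn_fw(z2, pd$g2, pd$be2, st$dec[[sn]]$bn2, training)
      dc$bn2 <- r$cache; st$dec[[sn]]$bn2 <- r$stats
      a2 <- r$y
    } else a2 <- z2
    dc$a2 <- a2
    x_cur <- pmax(a2, 0)
    cache$dec[[sn]] <- dc
  }

  cache$head_in <- x_cur
  logits <- conv_fw(x_cur, p$final$w, p$final$b)
  probs <- softmax4(logits)
  list(probs = probs,
       cache = if (want_cache) cache else NULL,
       stats = st)
}

# Backward pass: gradient of the loss with respect to every trainable
# parameter, given d(loss)/d(logits).  The cache must come from a
# forward_network(..., training = TRUE, want_cache = TRUE) call.
backward_network <- function(network, cache, dlogits) {
  cfg <- network$config
  p <- network$params
  d <- cfg$depth
  grads <- list(enc = list(), up = list(), att = list(), dec = list())

  r <- conv_bw(cache$head_in, p$final$w, dlogits)
  grads$final <- list(w = r$dw, b = r$db)
  dx <- r$dx

  dskip <- vector("list", d)
  for (s in seq_len(d - 1L)) {  # reverse of decoder execution order
    sn <- paste0("s", s)
    dc <- cache$dec[[sn]]
    pd <- p$dec[[sn]]
    da2 <- dx * (dc$a2 > 0)
    if (cfg$batch_norm) {
      bb <- bn_bw(da2, dc$bn2)
      dz2 <- bb$dx; dg2 <- bb$dgamma; dbe2 <- bb$dbeta
    } else { dz2 <- da2; dg2 <- dbe2 <- NULL }
    r <- conv_bw(dc$r1, pd$w2, dz2)
    dr1 <- r$dx; dw2 <- r$dw; db2 <- r$db
    da1 <- dr1 * (dc$a1 > 0)
    if (cfg$batch_norm) {
      bb <- bn_bw(da1, dc$bn1)
      dz1 <- bb$dx; dg1 <- bb$dgamma; dbe1 <- bb$dbeta
    } else { dz1 <- da1; dg1 <- dbe1 <- NULL }
    r <- conv_bw(dc$cat, pd$w1, dz1)
    dcat <- r$dx
    grads$dec[[sn]] <- list(w1 = r$dw, b1 = r$db, g1 = dg1, be1 = dbe1,
                            w2 = dw2, b2 = db2, g2 = dg2, be2 = dbe2)
    if (!cfg$batch_norm) grads$dec[[sn]][c("g1", "be1", "g2", "be2")] <- NULL

    nch <- dim(dc$g)[3]
    dg <- dcat[, , seq_len(nch), , drop = FALSE]
    dskip_g <- dcat[, , nch + seq_len(nch), , drop = FALSE]

    if (cfg$attention) {
      at <- dc$att
      pa <- p$att[[sn]]
      psi_e <- at$psi[, , rep(1L, nch), , drop = FALSE]
      dskip1 <- dskip_g * psi_e
      dpsi <- channel_sum(dskip_g * at$skip)
      dpsil <- dpsi * at$psi * (1 - at$psi)
      r <- conv_bw(at$f, pa$wpsi, dpsil)
      da <- r$dx * (at$a > 0)
      grads$att[[sn]] <- list(wpsi = r$dw, bpsi = r$db)
      r <- conv_bw(dc$g, pa$wg, da)
      grads$att[[sn]]$wg <- r$dw
      dg <- dg + r$dx
      r <- conv_bw(at$skip, pa$wx, da)
      grads$att[[sn]]$wx <- r$dw
      grads$att[[sn]]$bgx <- r$db
      dskip[[s]] <- dskip1 + r$dx
    } else {
      dskip[[s]] <- dskip_g
    }

    pu <- p$up[[sn]]
    if (cfg$upsample == "transposed") {
      r <- .upconv2_backward(dc$up_in, pu$w, dg)
      grads$up[[sn]] <- list(w = r$dw, b = r$db)
      dx <- r$dx
    } else {
      r <- conv_bw(dc$up_nn, pu$w, dg)
      grads$up[[sn]] <- list(w = r$dw, b = r$db)
      dx <- nn_upsample2_bw(r$dx)
    }
  }

  # dx now holds the gradient on the bottleneck encoder output
  denc <- dx
  for (s in rev(seq_len(d))) {
    sn <- paste0("s", s)
    e <- cache$enc[[sn]]
    pe <- p$enc[[sn]]
    dr2 <- if (s == d) denc
           else dskip[[s]] + .maxpool2_backward(dxin_next, e$pool_idx)
    da2 <- dr2 * (e$a2 > 0)
    if (cfg$batch_norm) {
      bb <- bn_bw(da2, e$bn2)
      dz2 <- bb$dx; dg2 <- bb$dgamma; dbe2 <- bb$dbeta
    } else { dz2 <- da2; dg2 <- dbe2 <- NULL }
    r <- conv_bw(e$r1, pe$w2, dz2)
    dw2 <- r$dw; db2 <- r$db
    da1 <- r$dx * (e$a1 > 0)
    if (cfg$batch_norm) {
      bb <- bn_bw(da1, e$bn1)
      dz1 <- bb$dx; dg1 <- bb$dgamma; dbe1 <- bb$dbeta
    } else { dz1 <- da1; dg1 <- dbe1 <- NULL }
    r <- conv_bw(e$xin, pe$w1, dz1)
    grads$enc[[sn]] <- list(w1 = r$dw, b1 = r$db, g1 = dg1, be1 = dbe1,
                            w2 = dw2, b2 = db2, g2 = dg2, be2 = dbe2)
    if (!cfg$batch_norm) grads$enc[[sn]][c("g1", "be1", "g2", "be2")] <- NULL
    dxin_next <- r$dx
  }
  grads
}

#' Predict class probabilities for a batch of sections
#'
#' Applies the network in inference mode to every 2D section of a slice
#' batch (or plain list of matrices), preserving order.  Each output is an
#' `(H, W, n_classes)` array of per-pixel class probabilities summing to 1.
#'
#' @param network A trained `sbf_network`.
#' @param batch A `slice_batch` from [reslice()], or a list of numeric
#'   matrices in \[0, 1\] sized to the network input side.
#' @param chunk Number of sections forwarded per internal batch.
#' @return List of probability arrays, one per input section.
#' @export
predict_slices <- function(network, batch, chunk = 16L) {
  slices <- if (inherits(batch, "slice_batch")) batch$slices else batch
  if (!length(slices)) return(list())
  side <- network$config$input_side
  for (sl in slices)
    if (!identical(dim(sl), c(side, side)))
      stop(sprintf("section size (%s) does not match network input side %d",
                   paste(dim(sl), collapse = "x"), side))
  out <- vector("list", length(slices))
  idx <- split(seq_along(slices), ceiling(seq_along(slices) / chunk))
  for (ii in idx) {
    x <- array(0, c(side, side, 1L, length(ii)))
    for (k in seq_along(ii)) x[, , 1L, k] <- slices[[ii[k]]]
    pr <- forward_network(network, x, training = FALSE)$probs
    for (k in seq_along(ii))
      out[[ii[k]]] <- array(pr[, , , k], dim(pr)[1:3])
  }
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint stores weights, batch-norm statistics, the network
#' configuration, any attached training configuration and history, and the
#' initialization seed.
#'
#' @param network An `sbf_network`.
#' @param path Checkpoint filename (RDS).
#' @return `path` (save) or the restored `sbf_network` (load).
#' @export
save_network <- function(network, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "sbf_network")) stop("not a network checkpoint: ", path)
  net
}
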