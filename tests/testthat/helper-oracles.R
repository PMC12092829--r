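# Independent oracles, deliberately written as direct/naive computations so
# they share no code path with the implementation they check.

# voxel-counting IoU
bf_iou <- function(pred, truth, class_id) {
  inter <- 0L
  uni <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == class_id
    t <- truth[i] == class_id
    if (p && t) inter <- inter + 1L
    if (p || t) uni <- uni + 1L
  }
  if (uni == 0L) NA_real_ else inter / uni
}

# soft Dice loss with smoothing convention matching 2*s on both sides
bf_dice_loss <- function(pred, truth, smooth = 1e-6) {
  nc <- dim(pred)[3]
  losses <- numeric(nc)
  for (c in seq_len(nc)) {
    p <- pred[, , c]
    t <- truth[, , c]
    dice <- (2 * sum(p * t) + 2 * smooth) /
      (sum(p) + sum(t) + 2 * smooth)
    losses[c] <- 1 - dice
  }
  mean(losses)
}

# 26-connected component count via BFS on voxel coordinates
bf_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  key <- function(v) paste(v, collapse = ",")
  remaining <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx))) assign(key(idx[r, ]), idx[r, ], remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ncomp <- 0L
  while (length(ls(remaining)) > 0L) {
    ncomp <- ncomp + 1L
    start <- get(ls(remaining)[1], remaining)
    queue <- list(start)
    rm(list = key(start), envir = remaining)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- v + offs[o, ]
        k <- key(nb)
        if (exists(k, remaining, inherits = FALSE)) {
          rm(list = k, envir = remaining)
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  ncomp
}

# truncated, border-renormalized 2D Gaussian blur by direct summation
bf_gaussian_blur <- function(slice, sigma, radius) {
  d <- dim(slice)
  out <- slice
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      num <- 0
      den <- 0
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
          w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
          num <- num + w * slice[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# minimum pairwise Euclidean distance between voxels of two instances
bf_min_instance_distance <- function(inst, a, b) {
  pa <- which(inst == a, arr.ind = TRUE)
  pb <- which(inst == b, arr.ind = TRUE)
  best <- Inf
  for (r in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[r, 1])^2 + (pb[, 2] - pa[r, 2])^2 +
      (pb[, 3] - pa[r, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# per-voxel mode filter, radius 1, direct neighbourhood counting
bf_mode_filter <- function(lab, radius = 1L) {
  d <- dim(lab)
  out <- lab
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zr <- max(1, z - radius):min(d[1], z + radius)
    yr <- max(1, y - radius):min(d[2], y + radius)
    xr <- max(1, x - radius):min(d[3], x + radius)
    nb <- as.vector(lab[zr, yr, xr])
    counts <- tabulate(nb + 1L, 6L)
    mx <- max(counts)
    modes <- which(counts == mx) - 1L
    ctr <- lab[z, y, x]
    out[z, y, x] <- if (ctr %in% modes) ctr else min(modes)
  }
  out
}

# brute-force fusion rule over the 3 x n_classes candidates:
# highest probability, ties to lowest class, then to earliest axis
bf_fuse <- function(pz, py, px) {
  d <- dim(pz)
  out <- array(0L, d[1:3])
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    best_p <- -Inf
    best_c <- NA_integer_
    for (vol in list(pz, py, px)) {
      for (c in seq_len(d[4])) {
        p <- vol[z, y, x, c]
        if (p > best_p || (p == best_p && (c - 1L) < best_c)) {
          best_p <- p
          best_c <- c - 1L
        }
      }
    }
    out[z, y, x] <- best_c
  }
  out
}
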