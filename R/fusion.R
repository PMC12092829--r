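# Multi-directional inference: predict section-by-section along each of the
# three volume axes, reassemble the per-class probabilities into the common
# (z, y, x) frame, select the globally most probable class per voxel, and
# clean residual speckle with a neighbourhood-mode filter.

#' Slice-wise inference along one axis
#'
#' Reslices the volume along the given axis, predicts every section with the
#' scanning network, and reassembles the per-class probabilities into the
#' original `(z, y, x)` frame so that volumes inferred along different axes
#' are voxel-aligned.
#'
#' @param network A trained `sbf_network`.
#' @param volume A preprocessed [raw_volume()] (normalized cube matching the
#'   network input side).
#' @param axis Inference direction, one of `"z"`, `"y"`, `"x"`.
#' @param chunk Sections per forward batch.
#' @return A `prob_volume`: list with `data` `(Z, Y, X, n_classes)` and
#'   `axis`.
#' @export
infer_direction <- function(network, volume, axis = c("z", "y", "x"),
                            chunk = 16L) {
  axis <- match.arg(axis)
  d <- dim(volume)
  side <- network$config$input_side
  if (!all(d == side))
    stop(sprintf("volume shape (%s) does not match network input side %d",
                 paste(d, collapse = ","), side))
  batch <- reslice(volume, axis)
  preds <- predict_slices(network, batch, chunk = chunk)
  nc <- network$config$n_classes
  P <- array(0, c(d, nc))
  for (i in seq_along(preds)) {
    switch(axis,
      z = { P[i, , , ] <- preds[[i]] },
      y = { P[, i, , ] <- preds[[i]] },
      x = { P[, , i, ] <- preds[[i]] })
  }
  structure(list(data = P, axis = axis, n_classes = nc,
                 spacing = volume$spacing),
            class = "prob_volume")
}

#' @export
print.prob_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("probability volume %d x %d x %d (z,y,x), %d classes, axis %s\n",
              d[1], d[2], d[3], d[4], x$axis))
  invisible(x)
}

#' Fuse directional predictions into a label volume
#'
#' Every voxel receives three per-class probability vectors, one per
#' inference direction; the selected class is the one holding the single
#' largest of the `3 x n_classes` values.  Exact ties are broken by the
#' lowest class index first, then by direction order z, y, x.  The fraction
#' of voxels on which the three per-direction argmax classes disagree is
#' attached as attribute `disagreement_fraction`.
#'
#' @param p_z,p_y,p_x Aligned `prob_volume`s from [infer_direction()].
#' @return A [label_volume()] with attribute `disagreement_fraction`.
#' @export
fuse_directions <- function(p_z, p_y, p_x) {
  vols <- list(p_z, p_y, p_x)
  dims <- lapply(vols, function(v) dim(v$data))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    stop("directional probability volumes have mismatched shapes")
  d <- dims[[1]]
  nc <- d[4]
  best_p <- array(-Inf, d[1:3])
  best_c <- array(0L, d[1:3])
  for (v in vols) {
    for (c in seq_len(nc)) {
      pc <- v$data[, , , c]
      upd <- (pc > best_p) | (pc == best_p & (c - 1L) < best_c)
      best_p[upd] <- pc[upd]
      best_c[upd] <- c - 1L
    }
  }
  # per-direction argmax agreement bookkeeping
  am <- lapply(vols, function(v) {
    a <- array(1L, d[1:3]); p <- v$data[, , , 1]
    for (c in seq_len(nc)[-1]) {
      pc <- v$data[, , , c]
      w <- pc > p
      a[w] <- c; p[w] <- pc[w]
    }
    a
  })
  disagree <- mean(am[[1]] != am[[2]] | am[[1]] != am[[3]])
  out <- label_volume(best_c, spacing = p_z$spacing)
  attr(out, "disagreement_fraction") <- disagree
  out
}

#' Mode-filter denoising of a label volume
#'
#' Categorical analogue of median filtering for the post-fusion cleanup:
#' each voxel takes the majority class of its `(2r+1)^3` neighbourhood
#' (truncated at volume borders).  Ties keep the centre voxel's class when
#' it is among the modes, otherwise the lowest class index.  Constant
#' volumes are unchanged.
#'
#' @param labels A [label_volume()].
#' @param radius Neighbourhood radius in voxels (>= 1).
#' @return The filtered [label_volume()].
#' @export
denoise_labels <- function(labels, radius = 1L) {
  stopifnot(inherits(labels, "sbf_labels"))
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be a positive integer")
  v <- labels$data
  d <- dim(v)
  nc <- 6L
  counts <- array(0L, c(d, nc))
  offs <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                      dx = -radius:radius)
  rng <- function(n, k) {
    if (k >= 0) list(dst = seq_len(n - k), src = seq_len(n - k) + k)
    else list(dst = seq_len(n + k) - k, src = seq_len(n + k))
  }
  for (o in seq_len(nrow(offs))) {
    zr <- rng(d[1], offs$dz[o]); yr <- rng(d[2], offs$dy[o]); xr <- rng(d[3], offs$dx[o])
    sub <- v[zr$src, yr$src, xr$src, drop = FALSE]
    for (c in seq_len(nc)) {
      counts[zr$dst, yr$dst, xr$dst, c] <-
        counts[zr$dst, yr$dst, xr$dst, c] + (sub == c - 1L)
    }
  }
  maxc <- counts[, , , 1]
  for (c in seq_len(nc)[-1]) maxc <- pmax(maxc, counts[, , , c])
  # lowest class index reaching the maximum count
  out <- array(NA_integer_, d)
  for (c in rev(seq_len(nc))) {
    w <- counts[, , , c] == maxc
    out[w] <- c - 1L
  }
  # centre label kept when it is among the modes
  lin <- cbind(as.vector(slice.index(v, 1)), as.vector(slice.index(v, 2)),
               as.vector(slice.index(v, 3)), as.vector(v) + 1L)
  centre_is_mode <- array(counts[lin] == as.vector(maxc), d)
  out[centre_is_mode] <- v[centre_is_mode]
  label_volume(out, spacing = labels$spacing)
}
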