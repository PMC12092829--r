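# Preprocessing chain: anisotropy correction -> bilateral denoising -> cube
# resize -> 0-1 normalization, plus the tri-axial reslicing used both for
# training-set augmentation and for multi-directional inference.
#
# Every geometric operation is nearest-neighbour, so intensity value sets are
# never blended and the identical operator applies to label volumes (classes
# must never be interpolated).

# Nearest-neighbour index map from n_out output voxels onto n_in input voxels
# under an output/input step-size ratio:  i_in = floor(i_out * ratio)
# (0-based), clamped.  ratio = d_out / d_in when resampling spacings, or
# n_in / n_out when resampling extents.
nn_index_map <- function(n_out, ratio, n_in) {
  idx <- floor((seq_len(n_out) - 1L) * ratio) + 1L
  pmin(pmax(idx, 1L), n_in)
}

#' Resample a volume to isotropic voxels
#'
#' FIB-SEM voxels are rectangular parallelepipeds: the milling step (dz)
#' usually differs from the in-plane pixel size.  This resamples the volume
#' by nearest-neighbour interpolation so that all three spacings equal the
#' finest of the three, restoring true aspect ratios.  Nearest-neighbour
#' creates no new intensity values, so the same operator is safe on label
#' volumes.
#'
#' @param volume A [raw_volume()] or [label_volume()] with known spacing.
#' @return The resampled volume with isotropic spacing.
#' @export
correct_anisotropy <- function(volume) {
  sp <- volume$spacing
  if (is.null(sp)) stop("volume spacing unknown")
  if (is_isotropic(sp)) return(volume)
  target <- min(sp)
  d <- dim(volume)
  n_out <- as.integer(round(d * sp / target))
  maps <- lapply(1:3, function(a) nn_index_map(n_out[a], target / sp[a], d[a]))
  out <- volume$data[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
  sp2 <- voxel_spacing(target, target, target)
  if (inherits(volume, "sbf_labels")) label_volume(out, spacing = sp2)
  else raw_volume(out, spacing = sp2, normalized = volume$normalized)
}

#' Bilateral denoising of the sectional images
#'
#' Applies a 2D bilateral filter to every z section (the acquired
#' cross-sectional images): each pixel becomes a weighted mean of its
#' neighbourhood, with weights that fall off both with spatial distance and
#' with intensity difference, so edges between compartments are preserved
#' while in-class noise is averaged away.  The output of each pixel is a
#' convex combination of input values, so the intensity range can only
#' contract.
#'
#' @param volume A [raw_volume()].
#' @param sigma_spatial Spatial Gaussian scale in voxels (window truncated at
#'   2 sigma).
#' @param sigma_range Intensity Gaussian scale; default 10% of the nominal
#'   intensity range (25.5 on 8-bit data, 0.1 on normalized data).
#' @return The filtered [raw_volume()] (continuous intensities within the
#'   input range).
#' @export
denoise_bilateral <- function(volume, sigma_spatial = 2, sigma_range = NULL) {
  stopifnot(inherits(volume, "sbf_raw"))
  if (sigma_spatial <= 0) stop("sigma_spatial must be positive")
  if (is.null(sigma_range))
    sigma_range <- 0.1 * if (volume$normalized) 1 else 255
  if (sigma_range <= 0) stop("sigma_range must be positive")
  v <- volume$data
  d <- dim(v)
  r <- ceiling(2 * sigma_spatial)
  num <- v  # centre offset: spatial weight 1, range weight 1
  den <- array(1, d)
  inv2s <- 1 / (2 * sigma_spatial^2)
  inv2r <- 1 / (2 * sigma_range^2)
  for (dy in -r:r) {
    ys <- shift_range(d[2], dy)
    for (dx in -r:r) {
      if (dy == 0 && dx == 0) next
      ws <- exp(-(dy^2 + dx^2) * inv2s)
      xs <- shift_range(d[3], dx)
      sub_dst <- v[, ys$dst, xs$dst, drop = FALSE]
      sub_src <- v[, ys$src, xs$src, drop = FALSE]
      w <- ws * exp(-(sub_src - sub_dst)^2 * inv2r)
      num[, ys$dst, xs$dst] <- num[, ys$dst, xs$dst, drop = FALSE] + w * sub_src
      den[, ys$dst, xs$dst] <- den[, ys$dst, xs$dst, drop = FALSE] + w
    }
  }
  raw_volume(num / den, spacing = volume$spacing,
             normalized = volume$normalized)
}

# destination/source index ranges for an in-plane shift by k
shift_range <- function(n, k) {
  if (k >= 0) list(dst = seq_len(n - k), src = seq_len(n - k) + k)
  else list(dst = seq_len(n + k) - k, src = seq_len(n + k))
}

#' Resize a volume to a cube
#'
#' Nearest-neighbour resample of all three axes to a common side length, the
#' fixed input size of the network.  The same operator applies to label
#' volumes so classes are never blended.
#'
#' @param volume A [raw_volume()] or [label_volume()].
#' @param side Target edge length in voxels (>= 16).
#' @return The resized volume; spacing is scaled per axis by the resampling
#'   factor.
#' @export
resize_to_cube <- function(volume, side) {
  side <- as.integer(side)
  if (side < 16L) stop("side must be >= 16")
  d <- dim(volume)
  if (all(d == side)) return(volume)
  maps <- lapply(1:3, function(a) nn_index_map(side, d[a] / side, d[a]))
  out <- volume$data[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
  sp <- volume$spacing
  sp2 <- voxel_spacing(sp[["dz"]] * d[1] / side, sp[["dy"]] * d[2] / side,
                       sp[["dx"]] * d[3] / side)
  if (inherits(volume, "sbf_labels")) label_volume(out, spacing = sp2)
  else raw_volume(out, spacing = sp2, normalized = volume$normalized)
}

#' Normalize intensities to 0-1
#'
#' Divides 8-bit intensities by 255, the network's expected input scale.
#'
#' @param volume An 8-bit [raw_volume()].
#' @return The normalized [raw_volume()].
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "sbf_raw"))
  if (volume$normalized) stop("volume is already normalized")
  raw_volume(volume$data / 255, spacing = volume$spacing, normalized = TRUE)
}

#' Reslice a volume into 2D sections along an axis
#'
#' Pure re-indexing, no interpolation: sections perpendicular to the chosen
#' axis, in axis order.  Along `z` these are the acquired cross-sections;
#' along `y` and `x` they are the newly generated lateral/anterior views used
#' for augmentation and multi-directional inference.  Requires isotropic
#' voxels (otherwise off-axis sections would be geometrically distorted);
#' correct anisotropy first.
#'
#' @param volume A [raw_volume()] or [label_volume()].
#' @param axis One of `"z"`, `"y"`, `"x"`.
#' @return A `slice_batch`: list of 2D sections plus bookkeeping
#'   (`axis`, `source_shape`, `kind`).
#' @export
reslice <- function(volume, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  if (!is_isotropic(volume$spacing))
    stop("reslice requires isotropic voxels; run correct_anisotropy() first")
  v <- volume$data
  d <- dim(v)
  slices <- switch(axis,
    z = lapply(seq_len(d[1]), function(i) v[i, , ]),
    y = lapply(seq_len(d[2]), function(j) v[, j, ]),
    x = lapply(seq_len(d[3]), function(k) v[, , k]))
  structure(list(slices = slices, axis = axis, source_shape = d,
                 kind = class(volume)[1],
                 spacing = volume$spacing,
                 normalized = if (inherits(volume, "sbf_raw")) volume$normalized else NULL),
            class = "slice_batch")
}

#' @export
print.slice_batch <- function(x, ...) {
  cat(sprintf("slice batch: %d sections of %s along axis %s from (%s)\n",
              length(x$slices), paste(dim(x$slices[[1]]), collapse = "x"),
              x$axis, paste(x$source_shape, collapse = ",")))
  invisible(x)
}

#' Reassemble a slice batch into a volume
#'
#' Exact inverse of [reslice()]: `unreslice(reslice(v, a))` is bit-identical
#' to `v` for every axis.
#'
#' @param batch A `slice_batch`.
#' @return The reassembled [raw_volume()] or [label_volume()].
#' @export
unreslice <- function(batch) {
  stopifnot(inherits(batch, "slice_batch"))
  d <- batch$source_shape
  v <- array(vector(typeof(batch$slices[[1]]), 1L), d)
  for (i in seq_along(batch$slices)) {
    switch(batch$axis,
      z = { v[i, , ] <- batch$slices[[i]] },
      y = { v[, i, ] <- batch$slices[[i]] },
      x = { v[, , i] <- batch$slices[[i]] })
  }
  if (batch$kind == "sbf_labels") label_volume(v, spacing = batch$spacing)
  else raw_volume(v, spacing = batch$spacing, normalized = batch$normalized)
}

#' Tri-axial training-set augmentation
#'
#' For every preprocessed (intensity, label) volume pair, emits paired 2D
#' sections along all three axes: the acquired cross-sections plus the
#' lateral and anterior views.  A cube of side S yields 3 S section pairs.
#'
#' @param volumes List of `list(raw = , labels = )` pairs; all volumes must be
#'   cubes of a common side and the intensity/label shapes must match.
#' @param step Keep every `step`-th section along each axis (default 1 =
#'   all sections).  Coarser steps give smaller, faster training epochs.
#' @return A list of section pairs, each
#'   `list(image, label, axis, index, volume)`, with a `manifest` attribute
#'   (data.frame of counts per volume and axis).
#' @export
augment_training_set <- function(volumes, step = 1L) {
  if (!length(volumes)) return(list())
  out <- list()
  rows <- list()
  for (vi in seq_along(volumes)) {
    pair <- volumes[[vi]]
    stopifnot_same_shape(pair$raw, pair$labels)
    d <- dim(pair$raw)
    if (length(unique(d)) != 1L)
      stop("augmentation expects cube volumes; run resize_to_cube() first")
    for (ax in c("z", "y", "x")) {
      rb <- reslice(pair$raw, ax)
      lb <- reslice(pair$labels, ax)
      keep <- seq(1L, length(rb$slices), by = step)
      for (i in keep) {
        out[[length(out) + 1L]] <- list(image = rb$slices[[i]],
                                        label = lb$slices[[i]],
                                        axis = ax, index = i, volume = vi)
      }
      rows[[length(rows) + 1L]] <- data.frame(volume = vi, axis = ax,
                                              sections = length(keep))
    }
  }
  attr(out, "manifest") <- do.call(rbind, rows)
  out
}

#' Run the full preprocessing chain
#'
#' Anisotropy correction, bilateral denoising, cube resize, then 0-1
#' normalization, in acquisition-pipeline order.  Labels passed through the
#' chain receive only the geometric steps.
#'
#' @param volume A [raw_volume()] (8-bit).
#' @param labels Optional matching [label_volume()].
#' @param side Cube side (default 256 at acquisition scale).
#' @param sigma_spatial,sigma_range Bilateral filter scales; see
#'   [denoise_bilateral()].
#' @return The preprocessed raw volume, or `list(raw, labels)` when labels
#'   are supplied.
#' @export
preprocess_chain <- function(volume, labels = NULL, side = 256,
                             sigma_spatial = 2, sigma_range = NULL) {
  v <- correct_anisotropy(volume)
  v <- denoise_bilateral(v, sigma_spatial, sigma_range)
  v <- resize_to_cube(v, side)
  v <- normalize_volume(v)
  if (is.null(labels)) return(v)
  l <- correct_anisotropy(labels)
  l <- resize_to_cube(l, side)
  list(raw = v, labels = l)
}
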