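# Extraction of individual cells from a multi-cell scene: per-section
# foreground masking (classical Otsu by default, or any pluggable 2D
# masker such as a promptable-segmentation model), seeded 3D watershed on
# the Euclidean distance transform, and per-cell cropping into single-cell
# volumes.

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance over a 256-bin histogram.  Returns
#' `NA` for degenerate (near-constant) inputs, where no bimodality exists.
#'
#' @param values Numeric vector of intensities.
#' @param range Intensity range spanned by the histogram.
#' @return Threshold value, or `NA`.
#' @export
otsu_threshold <- function(values, range = base::range(values)) {
  if (diff(range) <= 1e-12) return(NA_real_)
  breaks <- seq(range[1], range[2], length.out = 257L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), 256L)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  if (max(sb2) <= 0) return(NA_real_)
  mids[which.max(sb2)]
}

#' Foreground mask of a scene
#'
#' Separates cells from background section by section.  The default masker
#' computes one global Otsu threshold from the whole volume (robust on
#' sections containing no cell), binarizes each z section, removes speckle
#' by morphological opening, and fills enclosed holes (organelles darker
#' than the threshold lie inside the cytoplasm ring and must stay
#' foreground).  Any external per-section masker — e.g. an adapter around a
#' promptable segmentation model — can be plugged in as a function mapping
#' an intensity matrix to a logical mask of the same shape.
#'
#' @param volume A preprocessed [raw_volume()].
#' @param masker `NULL` for the default global-Otsu masker, or
#'   `function(slice) -> logical matrix`.
#' @param opening_size Diameter of the opening brush (odd integer; 0
#'   disables opening).  Default-masker only.
#' @return An `sbf_mask`: logical `(Z, Y, X)` array plus `provenance`
#'   (`"threshold"` or `"external-masker"`).
#' @export
mask_foreground <- function(volume, masker = NULL, opening_size = 3L) {
  stopifnot(inherits(volume, "sbf_raw"))
  v <- volume$data
  d <- dim(v)
  if (is.null(masker)) {
    thr <- otsu_threshold(as.vector(v))
    mask <- array(FALSE, d)
    if (is.na(thr)) {
      message("foreground masking: volume has no intensity bimodality; empty mask")
    } else {
      brush <- if (opening_size >= 3L) EBImage::makeBrush(opening_size, "disc")
      for (i in seq_len(d[1])) {
        m <- v[i, , ] > thr
        if (!is.null(brush)) m <- EBImage::opening(m, brush) > 0
        mask[i, , ] <- EBImage::fillHull(EBImage::Image(m * 1)) > 0
      }
      # organelles darker than the threshold leave holes; a hole need not be
      # enclosed in every sectioning plane (e.g. at a cell pole), so fill
      # along the two remaining axes as well
      for (j in seq_len(d[2]))
        mask[, j, ] <- EBImage::fillHull(EBImage::Image(mask[, j, ] * 1)) > 0
      for (k in seq_len(d[3]))
        mask[, , k] <- EBImage::fillHull(EBImage::Image(mask[, , k] * 1)) > 0
    }
    provenance <- "threshold"
  } else {
    mask <- array(FALSE, d)
    for (i in seq_len(d[1])) {
      m <- masker(v[i, , ])
      if (!is.logical(m) || !identical(dim(m), d[2:3]))
        stop("masker must return a logical matrix matching the section shape")
      mask[i, , ] <- m
    }
    provenance <- "external-masker"
  }
  structure(list(data = mask, provenance = provenance,
                 spacing = volume$spacing),
            class = "sbf_mask")
}

#' @export
print.sbf_mask <- function(x, ...) {
  cat(sprintf("foreground mask %s (%s): %.1f%% foreground\n",
              paste(dim(x$data), collapse = " x "), x$provenance,
              100 * mean(x$data)))
  invisible(x)
}

#' Separate cells by seeded 3D watershed
#'
#' Computes the Euclidean distance transform of the foreground mask, finds
#' seeds as its h-maxima — distance peaks with prominence of at least `h`,
#' one seed per peak; the discrete staircase plateaus of the transform are
#' flattened by morphological reconstruction so a single cell body never
#' yields more than one seed — suppressed to a minimum pairwise
#' separation, then floods the mask on the negated distance transform.
#' The instance count equals the seed count; flooding-order ties are
#' resolved by lexicographic voxel order, so the labelling is
#' deterministic.
#'
#' @param mask An `sbf_mask` (or logical array).
#' @param min_seed_distance Minimum Euclidean distance in voxels between
#'   seeds; about the expected cell radius.
#' @param h Prominence threshold in voxels: a secondary distance peak
#'   splits off its own cell only if it rises at least `h` above the saddle
#'   connecting it to a deeper peak.  Default `min_seed_distance / 4`.
#'   Smaller values oversplit (a strongly pinched dumbbell separates into
#'   its two daughter lobes); larger values merge fused neighbours.
#' @return An [instance_volume()]; an empty mask yields zero instances.
#'   Mask components too shallow to host a seed (debris smaller than `h`)
#'   stay unlabelled: they are not cells.
#' @export
watershed_cells <- function(mask, min_seed_distance = 10,
                            h = min_seed_distance / 4) {
  m <- if (inherits(mask, "sbf_mask")) mask$data else mask
  if (!is.logical(m) || length(dim(m)) != 3L)
    stop("mask must be a logical 3D array")
  sp <- if (inherits(mask, "sbf_mask")) mask$spacing else voxel_spacing(1, 1, 1)
  if (!any(m))
    return(instance_volume(array(0L, dim(m)), spacing = sp))
  dist <- sqrt(.edt3d_sq(m))
  seeds <- .hmax_seeds(dist, h, min_seed_distance)
  lab <- .watershed_flood(m, dist, seeds)
  instance_volume(lab, spacing = sp)
}

#' Crop each cell instance into its own volume
#'
#' One crop per instance: the instance bounding box dilated by `margin` and
#' clamped to the scene, with voxels belonging to other instances inside the
#' box blanked to the scene background intensity, so each crop centrally
#' contains exactly one cell.
#'
#' @param volume The scene [raw_volume()].
#' @param instances Aligned [instance_volume()] from [watershed_cells()].
#' @param margin Nonnegative dilation of the bounding box in voxels.
#' @return A list of `cell_crop`s: `volume` (single-cell [raw_volume()]),
#'   `instance`, `bbox` (3 x 2 matrix in scene coordinates), `margin`.
#' @export
crop_cells <- function(volume, instances, margin = 4L) {
  stopifnot(inherits(volume, "sbf_raw"), inherits(instances, "sbf_instances"))
  stopifnot_same_shape(volume$data, instances$data)
  margin <- as.integer(margin)
  if (is.na(margin) || margin < 0L) stop("margin must be nonnegative")
  K <- instances$n_instances
  if (K == 0L) return(list())
  d <- dim(volume$data)
  bg <- median(volume$data[instances$data == 0L])
  if (!volume$normalized) bg <- round(bg)
  lapply(seq_len(K), function(k) {
    w <- which(instances$data == k, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - margin, 1L)
    hi <- pmin(apply(w, 2, max) + margin, d)
    sub <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    inst_sub <- instances$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                               drop = FALSE]
    sub[inst_sub != 0L & inst_sub != k] <- bg
    structure(list(volume = raw_volume(sub, spacing = volume$spacing,
                                       normalized = volume$normalized),
                   instance = k,
                   bbox = cbind(lo = lo, hi = hi),
                   margin = margin),
              class = "cell_crop")
  })
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("cell crop (instance %d): %s voxels, box z %d..%d, y %d..%d, x %d..%d\n",
              x$instance, paste(dim(x$volume$data), collapse = " x "),
              x$bbox[1, 1], x$bbox[1, 2], x$bbox[2, 1], x$bbox[2, 2],
              x$bbox[3, 1], x$bbox[3, 2]))
  invisible(x)
}

#' Full cell-extraction pipeline
#'
#' Foreground masking, seeded 3D watershed, and per-cell cropping, producing
#' one single-cell volume per detected cell plus a manifest of what was
#' done.
#'
#' @param scene A preprocessed [raw_volume()] containing several cells.
#' @param masker Optional external per-section masker (see
#'   [mask_foreground()]).
#' @param min_seed_distance,h See [watershed_cells()].
#' @param margin See [crop_cells()].
#' @return A list: `crops`, `instances`, `mask`, and `manifest` (instance
#'   count, bounding boxes, parameters, masker provenance).
#' @export
extract_pipeline <- function(scene, masker = NULL, min_seed_distance = 10,
                             h = min_seed_distance / 4, margin = 4L) {
  mask <- mask_foreground(scene, masker = masker)
  instances <- watershed_cells(mask, min_seed_distance = min_seed_distance,
                               h = h)
  crops <- crop_cells(scene, instances, margin = margin)
  manifest <- list(
    n_cells = instances$n_instances,
    boxes = lapply(crops, function(cr) cr$bbox),
    params = list(min_seed_distance = min_seed_distance, h = h,
                  margin = margin),
    masker = mask$provenance)
  list(crops = crops, instances = instances, mask = mask,
       manifest = manifest)
}
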