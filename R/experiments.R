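# Desk-scale experiment drivers: phantom-based training/evaluation runs used
# by the test suite and the acceptance script.  Problem sizes default to the
# package's desk-scale study conditions: 64-voxel cubes, a base-8 depth-4
# network, 20 training phantoms spanning the five division stages, 5 epochs.

#' Axis-aligned Gaussian blur
#'
#' Blurs a volume along one axis only (1D Gaussian, truncated at 3 sigma,
#' renormalized at the borders), emulating direction-dependent degradation
#' such as the smearing of structure along the milling direction.  Useful
#' for studying how inference direction interacts with anisotropic image
#' quality.
#'
#' @param volume A [raw_volume()].
#' @param sigma Gaussian scale in voxels.
#' @param axis Axis to blur along: `"z"`, `"y"` or `"x"`.
#' @return The blurred [raw_volume()].
#' @export
degrade_blur <- function(volume, sigma = 1.5, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  stopifnot(inherits(volume, "sbf_raw"))
  if (sigma <= 0) stop("sigma must be positive")
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  v <- volume$data
  d <- dim(v)
  ax <- match(axis, c("z", "y", "x"))
  num <- v * k[r + 1]
  den <- array(k[r + 1], d)
  for (o in c(-r:-1, 1:r)) {
    n <- d[ax]
    if (o >= 0) { dst <- seq_len(n - o); src <- dst + o }
    else { dst <- seq_len(n + o) - o; src <- seq_len(n + o) }
    w <- k[o + r + 1]
    if (ax == 1) {
      num[dst, , ] <- num[dst, , ] + w * v[src, , ]
      den[dst, , ] <- den[dst, , ] + w
    } else if (ax == 2) {
      num[, dst, ] <- num[, dst, ] + w * v[, src, ]
      den[, dst, ] <- den[, dst, ] + w
    } else {
      num[, , dst] <- num[, , dst] + w * v[, , src]
      den[, , dst] <- den[, , dst] + w
    }
  }
  raw_volume(num / den, spacing = volume$spacing,
             normalized = volume$normalized)
}

#' Train-and-evaluate segmentation experiment on phantoms
#'
#' Generates training phantoms spanning the five division stages, trains
#' the scanning attention U-Net on tri-axially augmented sections, and
#' scores held-out phantoms (one per stage) by per-class IoU.  The
#' defaults are the package's desk-scale study conditions; they fit in CPU
#' minutes rather than GPU hours.
#'
#' @param seed Master seed: phantom generation, weight initialization and
#'   data order all derive from it.
#' @param n_train,n_holdout Numbers of training and held-out phantoms
#'   (stages cycle 1..5).
#' @param cube_side Phantom volume side (and network input side).
#' @param base_channels,depth Network scale.
#' @param epochs,base_lr,batch_size Training schedule.  The desk-scale
#'   default base rate 3e-3 reflects the small number of optimizer steps;
#'   acquisition-scale runs use [train_config()]'s 1e-5 default.
#' @param section_step Keep every `section_step`-th section per axis when
#'   augmenting (see [augment_training_set()]).
#' @param directions 1 to evaluate z-direction inference only, 3 for fused
#'   tri-directional inference.
#' @param denoise_radius Mode-filter radius applied to predictions (0 =
#'   none).
#' @return A list: `network`, `history`, `holdout` (per-phantom metrics
#'   data.frame with stage), and `class_iou` (mean IoU per class over the
#'   holdout phantoms, undefined entries excluded).
#' @export
segmentation_experiment <- function(seed = 1L, n_train = 20L, n_holdout = 5L,
                                    cube_side = 64L, base_channels = 8L,
                                    depth = 4L, epochs = 5L, base_lr = 3e-3,
                                    batch_size = 8L, section_step = 8L,
                                    directions = 1L, denoise_radius = 0L) {
  stages_tr <- rep_len(1:5, n_train)
  train_pairs <- lapply(seq_len(n_train), function(i) {
    ph <- generate_phantom(phantom_spec(stage = stages_tr[i],
                                        cube_side = cube_side,
                                        seed = seed * 1000L + i))
    list(raw = normalize_volume(ph$raw), labels = ph$labels)
  })
  sections <- augment_training_set(train_pairs, step = section_step)

  net <- build_network(network_config(input_side = cube_side,
                                      base_channels = base_channels,
                                      depth = depth),
                       seed = seed)
  tc <- train_config(base_lr = base_lr, epochs = epochs,
                     batch_size = batch_size, seed = seed)
  fit <- train_network(net, sections, config = tc)

  stages_ho <- rep_len(1:5, n_holdout)
  rows <- list()
  for (i in seq_len(n_holdout)) {
    ph <- generate_phantom(phantom_spec(stage = stages_ho[i],
                                        cube_side = cube_side,
                                        seed = seed * 1000L + 500L + i))
    v <- normalize_volume(ph$raw)
    pred <- if (directions >= 3L) {
      fuse_directions(infer_direction(fit$network, v, "z"),
                      infer_direction(fit$network, v, "y"),
                      infer_direction(fit$network, v, "x"))
    } else {
      pz <- infer_direction(fit$network, v, "z")
      fuse_directions(pz, pz, pz)
    }
    if (denoise_radius >= 1L) pred <- denoise_labels(pred, denoise_radius)
    m <- evaluate_volume(pred, ph$labels)
    m$stage <- stages_ho[i]
    m$phantom <- i
    rows[[i]] <- m
  }
  holdout <- do.call(rbind, rows)
  cls <- vapply(sort(unique(holdout$class_id)), function(cid) {
    e <- holdout[holdout$class_id == cid & holdout$defined, "iou"]
    if (length(e)) mean(e) else NA_real_
  }, numeric(1))
  names(cls) <- names(sbf_classes)[match(sort(unique(holdout$class_id)),
                                         sbf_classes)]
  list(network = fit$network, history = fit$history, holdout = holdout,
       class_iou = cls)
}

#' Directional-degradation fusion experiment
#'
#' For each seed, generates a phantom, blurs it along one axis, runs
#' inference along all three axes, and compares the mean foreground IoU of
#' each single direction against the three-direction fusion.  Quantifies
#' whether fusing helps (or at least costs little) when one viewing
#' direction is degraded.
#'
#' @param network A trained `sbf_network`.
#' @param seeds Integer vector of phantom seeds.
#' @param blur_sigma Gaussian scale of the axis-aligned blur.
#' @param blur_axis Axis to degrade.
#' @param denoise_radius Mode-filter radius applied to all compared label
#'   volumes (0 = none).
#' @return A data.frame with one row per seed: per-direction and fused mean
#'   foreground IoU.
#' @export
fusion_experiment <- function(network, seeds = 1:10, blur_sigma = 1.5,
                              blur_axis = "z", denoise_radius = 0L) {
  side <- network$config$input_side
  rows <- lapply(seeds, function(s) {
    ph <- generate_phantom(phantom_spec(stage = ((s - 1L) %% 5L) + 1L,
                                        cube_side = side,
                                        seed = 77000L + s))
    v <- normalize_volume(degrade_blur(ph$raw, sigma = blur_sigma,
                                       axis = blur_axis))
    pv <- list(z = infer_direction(network, v, "z"),
               y = infer_direction(network, v, "y"),
               x = infer_direction(network, v, "x"))
    score <- function(lab) {
      if (denoise_radius >= 1L) lab <- denoise_labels(lab, denoise_radius)
      mean_iou(evaluate_volume(lab, ph$labels))
    }
    data.frame(seed = s,
               iou_z = score(fuse_directions(pv$z, pv$z, pv$z)),
               iou_y = score(fuse_directions(pv$y, pv$y, pv$y)),
               iou_x = score(fuse_directions(pv$x, pv$x, pv$x)),
               iou_fused = score(fuse_directions(pv$z, pv$y, pv$x)))
  })
  do.call(rbind, rows)
}

#' Multi-cell extraction experiment
#'
#' Generates seeded multi-cell scenes for each requested cell count, runs
#' the full extraction pipeline, and records whether the watershed
#' recovered exactly the true number of cells and whether every crop
#' contains exactly one ground-truth cell (instance-majority check within
#' the crop's core bounding box).
#'
#' @param cell_counts Cell counts K to test.
#' @param n_scenes Seeded scenes per K.
#' @param seed Base seed.
#' @param min_seed_distance,margin Extraction parameters.
#' @param cell_radius,min_gap,scene_shape Scene parameters.
#' @return A data.frame with one row per scene: K, seed, detected count,
#'   `count_ok`, `crops_ok`.
#' @export
extraction_experiment <- function(cell_counts = 2:5, n_scenes = 20L,
                                  seed = 1L, min_seed_distance = 10,
                                  margin = 4L, cell_radius = 11L,
                                  min_gap = 6L,
                                  scene_shape = c(80L, 120L, 120L)) {
  rows <- list()
  for (K in cell_counts) {
    for (i in seq_len(n_scenes)) {
      sc <- generate_scene(scene_spec(n_cells = K,
                                      volume_shape = scene_shape,
                                      min_gap = min_gap,
                                      cell_radius = cell_radius,
                                      seed = seed * 10000L + K * 100L + i))
      res <- extract_pipeline(sc$raw, min_seed_distance = min_seed_distance,
                              margin = margin)
      count_ok <- res$instances$n_instances == K
      crops_ok <- count_ok && all(vapply(res$crops, function(cr) {
        b <- cr$bbox
        true_inside <- sc$instances$data[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                                         b[3, 1]:b[3, 2]]
        ids <- setdiff(unique(as.vector(true_inside)), 0L)
        # the crop must contain the voxels of exactly one true cell entirely
        length(ids) >= 1L && {
          main <- ids[which.max(tabulate(true_inside + 1L)[ids + 1L])]
          others <- setdiff(ids, main)
          # other cells may only graze the margin; the dominant cell must be
          # fully inside the box
          n_main_in <- sum(true_inside == main)
          n_main_tot <- sum(sc$instances$data == main)
          n_main_in == n_main_tot &&
            all(vapply(others, function(o)
              sum(true_inside == o) < 0.5 * sum(sc$instances$data == o),
              logical(1)))
        }
      }, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(K = K, scene = i,
                                              detected = res$instances$n_instances,
                                              count_ok = count_ok,
                                              crops_ok = crops_ok)
    }
  }
  do.call(rbind, rows)
}
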