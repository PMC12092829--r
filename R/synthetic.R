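# Synthetic dividing-cell phantoms.
#
# The generator emulates the structure of single-cell SBF volumes of a
# unicellular red alga: one cell per volume, six voxel classes, five division
# stages.  The cell body is an ellipsoid that pinches into a dumbbell of two
# daughter lobes as division progresses; each organelle is a ball placed
# inside the cell, present as a single body in early stages and as one body
# per daughter lobe late in division.  Intensities are drawn per class around
# a class mean, with the mitochondrion, nucleus and peroxisome means placed
# deliberately close to the background mean: in the real images those
# compartments have brightness similar to the background, which is what makes
# them hard, so the phantoms must reproduce that confound.

#' Phantom cell specification
#'
#' Parameters of one synthetic single-cell volume.
#'
#' @param stage Division stage 1..5.  Stage 1 is interphase (single
#'   ellipsoidal cell, every organelle a single body); stage 5 is the end of
#'   mitosis (strongly pinched dumbbell, every organelle split equally
#'   between the two daughter lobes).
#' @param cube_side Edge length of the cubic volume in voxels (>= 16).
#'   Default 64; 256 matches full acquisition-scale processing.
#' @param spacing A [voxel_spacing()] for the generated volume.
#' @param cell_radius Base cell radius in voxels.  Default scales with the
#'   cube (about a quarter of the side, so the pinched stage-5 dumbbell still
#'   fits).
#' @param organelle_fractions Named target volume fractions of the cell
#'   occupied by plastid, mitochondrion, peroxisome and nucleus.  Must be
#'   nonnegative and sum to < 1; the remainder is cytoplasm.  The defaults
#'   pack reliably for `cube_side` >= 48; in smaller volumes the
#'   post-division stages (two bodies per organelle in small daughter
#'   lobes) may be geometrically unplaceable at full size and need reduced
#'   fractions.
#' @param intensity_means Named per-class mean brightness (0..255).
#' @param intensity_sds Named per-class Gaussian noise scale.
#' @param constriction Dumbbell pinch in \[0, 1\]; `NULL` (default) derives it
#'   from the stage as `(stage - 1) / 4`, i.e. 0 at stage 1 growing to 1 at
#'   stage 5.
#' @param gain_jitter Standard deviation of an optional per-slice
#'   multiplicative gain (emulates section-to-section SEM gain variation);
#'   0 disables it.
#' @param seed RNG seed; all randomness in the generator flows through it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(stage,
                         cube_side = 64L,
                         spacing = voxel_spacing(1, 1, 1),
                         cell_radius = NULL,
                         organelle_fractions = c(plastid = 0.08,
                                                 mitochondrion = 0.02,
                                                 peroxisome = 0.008,
                                                 nucleus = 0.04),
                         intensity_means = c(background = 40, cytoplasm = 95,
                                             plastid = 200, mitochondrion = 65,
                                             peroxisome = 70, nucleus = 52),
                         intensity_sds = c(background = 10, cytoplasm = 10,
                                           plastid = 10, mitochondrion = 10,
                                           peroxisome = 10, nucleus = 10),
                         constriction = NULL,
                         gain_jitter = 0,
                         seed = 1L) {
  stage <- as.integer(stage)
  if (!stage %in% 1:5) stop("stage must be an integer in 1..5")
  cube_side <- as.integer(cube_side)
  if (cube_side < 16L) stop("cube_side must be >= 16")
  if (is.null(cell_radius)) cell_radius <- round(0.26 * cube_side)
  if (any(organelle_fractions < 0)) stop("organelle fractions must be nonnegative")
  if (sum(organelle_fractions) >= 1)
    stop("organelle fractions must sum to < 1 (remainder is cytoplasm)")
  need <- c("plastid", "mitochondrion", "peroxisome", "nucleus")
  if (!all(need %in% names(organelle_fractions)))
    stop("organelle_fractions must name: ", paste(need, collapse = ", "))
  if (is.null(constriction)) constriction <- (stage - 1) / 4
  if (constriction < 0 || constriction > 1) stop("constriction must be in [0, 1]")
  structure(list(stage = stage, cube_side = cube_side, spacing = spacing,
                 cell_radius = cell_radius,
                 organelle_fractions = organelle_fractions,
                 intensity_means = intensity_means,
                 intensity_sds = intensity_sds,
                 constriction = constriction,
                 gain_jitter = gain_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Dumbbell geometry shared by phantom and scene generation.  Lobes are
# ellipsoids slightly elongated along a common major axis; their centre
# separation grows with constriction while the lobe radius shrinks, so the
# mid-plane neck narrows monotonically with stage.
phantom_geometry <- function(spec, axis_u) {
  cst <- spec$constriction
  r <- spec$cell_radius
  lobe_r <- r * (1 - 0.25 * cst)
  offset <- 1.1 * cst * lobe_r
  elong <- 1.15  # fixed major-axis elongation of each lobe
  list(lobe_r = lobe_r, offset = offset, elong = elong,
       extent = offset + elong * lobe_r, axis_u = axis_u)
}

# Voxel-centre coordinate arrays for a (Z,Y,X) grid.
grid_coords <- function(dm) {
  list(z = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm),
       y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm),
       x = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm))
}

# Boolean mask of an ellipsoid with semi-axis a along unit vector u and b on
# the two perpendicular directions, centred at ctr.
ellipsoid_mask <- function(gc, ctr, u, a, b) {
  dz <- gc$z - ctr[1]; dy <- gc$y - ctr[2]; dx <- gc$x - ctr[3]
  proj <- dz * u[1] + dy * u[2] + dx * u[3]
  perp2 <- pmax(dz^2 + dy^2 + dx^2 - proj^2, 0)
  (proj / a)^2 + perp2 / b^2 <= 1
}

sphere_mask <- function(gc, ctr, r) {
  (gc$z - ctr[1])^2 + (gc$y - ctr[2])^2 + (gc$x - ctr[3])^2 <= r^2
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Uniform point in a ball of radius r around ctr.
runif_ball <- function(ctr, r) {
  repeat {
    p <- runif(3, -r, r)
    if (sum(p^2) <= r^2) return(ctr + p)
  }
}

# Place the organelle bodies of one cell.  Returns a list of
# list(class_id, centre, radius).  Placement is purely geometric (balls with
# clearance margins), so bodies never touch each other or the cell surface.
# The fraction-derived radius is a target: when a body cannot be placed at
# full size inside the remaining free space it is shrunk stepwise, so
# crowded late-stage lobes stay generatable while class identity, component
# counts and relative size ordering are preserved.  If a layout still dead
# ends (e.g. an early body landed dead centre and blocks every later one),
# the whole layout is redrawn.
place_organelles <- function(spec, geom, centre, max_restarts = 25L) {
  for (rs in seq_len(max_restarts)) {
    placed <- try(place_organelles_once(spec, geom, centre), silent = TRUE)
    if (!inherits(placed, "try-error")) return(placed)
  }
  stop(attr(placed, "condition")$message)
}

place_organelles_once <- function(spec, geom, centre, max_attempts = 150L) {
  stage <- spec$stage
  n_comp <- if (stage <= 3L) 1L else 2L
  lobe_centres <- list(centre + geom$offset * geom$axis_u,
                       centre - geom$offset * geom$axis_u)
  cell_volume <- 2 * (4 / 3) * pi * geom$elong * geom$lobe_r^3 -
    overlap_correction(geom)
  # class order big-to-small makes rejection placement robust
  order_cls <- c(plastid = 2L, nucleus = 5L, mitochondrion = 3L,
                 peroxisome = 4L)
  placed <- list()
  for (nm in names(order_cls)) {
    frac <- spec$organelle_fractions[[nm]]
    if (frac <= 0) next
    r_target <- (3 * frac * cell_volume / (4 * pi * n_comp))^(1 / 3)
    for (k in seq_len(n_comp)) {
      host <- if (n_comp == 1L) centre else lobe_centres[[k]]
      r_comp <- max(r_target, 1)
      ok <- FALSE
      for (shrink in 1:12) {
        # sampling region covers the whole containment region (both lobes
        # when the body may sit anywhere in the cell); every 3rd draw sits on
        # the region boundary, which reaches tight near-antipodal layouts
        samp_r <- (if (n_comp == 1L) geom$offset else 0) +
          geom$lobe_r - r_comp - 1.5
        if (samp_r > 0) {
          for (att in seq_len(max_attempts)) {
            ctr_k <- if (att %% 3L == 0L)
              host + samp_r * random_unit_vector()
            else runif_ball(host, samp_r)
            # containment: inside the nearer lobe ball with margin
            d1 <- sqrt(sum((ctr_k - lobe_centres[[1]])^2))
            d2 <- sqrt(sum((ctr_k - lobe_centres[[2]])^2))
            if (min(d1, d2) + r_comp > geom$lobe_r - 1.5) next
            # disjoint from previously placed bodies (clearance > sqrt(3)
            # voxels so 26-connected components never merge)
            clear <- all(vapply(placed, function(p)
              sqrt(sum((ctr_k - p$centre)^2)) >= p$radius + r_comp + 1.8,
              logical(1)))
            if (clear) {
              placed[[length(placed) + 1L]] <-
                list(class_id = order_cls[[nm]], centre = ctr_k,
                     radius = r_comp)
              ok <- TRUE
              break
            }
          }
        }
        if (ok) break
        r_comp <- r_comp * 0.85
        if (r_comp < 1.0) break
      }
      if (!ok)
        stop(sprintf("could not place organelle '%s' (stage %d, cell radius %g, lobe radius %.1f)",
                     nm, stage, spec$cell_radius, geom$lobe_r))
    }
  }
  placed
}

# Sphere-sphere lens volume correction for the two-lobe union, scaled by the
# lobe elongation.  Exact value is unimportant; it only sets organelle target
# volumes.
overlap_correction <- function(geom) {
  d <- 2 * geom$offset
  r <- geom$lobe_r
  if (d >= 2 * r) return(0)
  geom$elong * (pi / 12) * (4 * r + d) * (2 * r - d)^2
}

#' Generate a phantom single-cell volume
#'
#' Produces a synthetic intensity volume and its ground-truth label volume
#' from a [phantom_spec()].  Deterministic given the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `raw` ([raw_volume()], 8-bit), `labels`
#'   ([label_volume()]) and `meta` (geometry actually used: lobe centres,
#'   radii, organelle placements).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- spec$cube_side
  withr::local_seed(spec$seed)

  axis_u <- random_unit_vector()
  geom <- phantom_geometry(spec, axis_u)
  centre <- rep((side + 1) / 2, 3)
  if (geom$extent > side / 2 - 2)
    stop(sprintf("cell (extent %.1f voxels) does not fit in a %d-cube",
                 geom$extent, side))

  dm <- c(side, side, side)
  gc <- grid_coords(dm)
  lobe1 <- centre + geom$offset * axis_u
  lobe2 <- centre - geom$offset * axis_u
  cell <- ellipsoid_mask(gc, lobe1, axis_u, geom$elong * geom$lobe_r, geom$lobe_r) |
    ellipsoid_mask(gc, lobe2, axis_u, geom$elong * geom$lobe_r, geom$lobe_r)

  labels <- array(0L, dm)
  labels[cell] <- 1L  # cytoplasm
  placed <- place_organelles(spec, geom, centre)
  for (p in placed) labels[sphere_mask(gc, p$centre, p$radius)] <- p$class_id

  mu <- spec$intensity_means[names(sbf_classes)][labels + 1L]
  sdv <- spec$intensity_sds[names(sbf_classes)][labels + 1L]
  vals <- mu + rnorm(length(labels)) * sdv
  if (spec$gain_jitter > 0) {
    gains <- 1 + rnorm(side) * spec$gain_jitter
    vals <- vals * gains[gc$z]
  }
  vals <- pmin(pmax(round(vals), 0), 255)
  raw <- array(as.integer(vals), dm)

  list(raw = raw_volume(raw, spacing = spec$spacing),
       labels = label_volume(labels, spacing = spec$spacing),
       meta = list(axis_u = axis_u, lobe_centres = list(lobe1, lobe2),
                   lobe_r = geom$lobe_r, offset = geom$offset,
                   elong = geom$elong, organelles = placed))
}

#' Multi-cell scene specification
#'
#' Parameters of a synthetic scene containing several cells separated by
#' background, emulating a large acquisition of a multi-cell sample.
#'
#' @param n_cells Number of cells (>= 1).
#' @param volume_shape Integer vector `(Z, Y, X)` of the scene in voxels.
#' @param min_gap Minimum number of background voxels between any two cells.
#' @param cell_radius Base radius of each cell in voxels.
#' @param stages Per-cell division stages (recycled).  Defaults to stages
#'   1..3: by late mitosis a dumbbell is morphologically two daughter cells
#'   and instance separation is expected to split it.
#' @param spacing A [voxel_spacing()].
#' @param intensity_means,intensity_sds As in [phantom_spec()].
#' @param gain_jitter As in [phantom_spec()].
#' @param seed RNG seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_cells,
                       volume_shape = c(64L, 96L, 96L),
                       min_gap = 4L,
                       cell_radius = 11L,
                       stages = NULL,
                       spacing = voxel_spacing(1, 1, 1),
                       intensity_means = c(background = 40, cytoplasm = 95,
                                           plastid = 200, mitochondrion = 65,
                                           peroxisome = 70, nucleus = 52),
                       intensity_sds = c(background = 10, cytoplasm = 10,
                                         plastid = 10, mitochondrion = 10,
                                         peroxisome = 10, nucleus = 10),
                       gain_jitter = 0,
                       seed = 1L) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be >= 1")
  if (length(volume_shape) != 3L) stop("volume_shape must be (Z, Y, X)")
  if (min_gap < 0) stop("min_gap must be nonnegative")
  if (is.null(stages)) stages <- rep_len(1:3, n_cells)
  stages <- rep_len(as.integer(stages), n_cells)
  structure(list(n_cells = n_cells, volume_shape = as.integer(volume_shape),
                 min_gap = as.integer(min_gap), cell_radius = cell_radius,
                 stages = stages, spacing = spacing,
                 intensity_means = intensity_means,
                 intensity_sds = intensity_sds, gain_jitter = gain_jitter,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a multi-cell scene
#'
#' Places `n_cells` phantom cells in one volume by rejection sampling so that
#' any two cells are separated by at least `min_gap` background voxels, and
#' renders intensities, per-cell ground-truth instances, and merged class
#' labels.  Deterministic given the spec seed.
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Total placement attempt budget before giving up.
#' @return A list with elements `raw` ([raw_volume()]),
#'   `instances` ([instance_volume()]) and `labels` ([label_volume()]).
#' @export
generate_scene <- function(spec, max_attempts = 2000L) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::local_seed(spec$seed)
  dm <- spec$volume_shape

  # First pick per-cell geometry, then place bounding spheres.
  cells <- lapply(seq_len(spec$n_cells), function(k) {
    ps <- phantom_spec(stage = spec$stages[k], cube_side = 64L,
                       cell_radius = spec$cell_radius,
                       intensity_means = spec$intensity_means,
                       intensity_sds = spec$intensity_sds,
                       seed = spec$seed + k)  # seed field unused here
    u <- random_unit_vector()
    list(spec = ps, geom = phantom_geometry(ps, u))
  })
  ext <- vapply(cells, function(cl) cl$geom$extent, numeric(1))
  if (any(2 * (ext + 2) >= dm[1]))
    stop(sprintf("cells (extent %.1f) too large for scene shape (%s)",
                 max(ext), paste(dm, collapse = ",")))

  centres <- vector("list", spec$n_cells)
  attempts <- 0L
  for (k in seq_len(spec$n_cells)) {
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("scene placement budget exhausted after %d attempts ",
                            "(n_cells=%d, shape=%s, min_gap=%d, cell_radius=%g)"),
                     max_attempts, spec$n_cells, paste(dm, collapse = "x"),
                     spec$min_gap, spec$cell_radius))
      ctr <- vapply(1:3, function(a)
        runif(1, ext[k] + 2, dm[a] - ext[k] - 1), numeric(1))
      ok <- TRUE
      for (j in seq_len(k - 1L)) {
        if (sqrt(sum((ctr - centres[[j]])^2)) <
            ext[k] + ext[j] + spec$min_gap) { ok <- FALSE; break }
      }
      if (ok) { centres[[k]] <- ctr; placed <- TRUE }
    }
  }

  gc <- grid_coords(dm)
  labels <- array(0L, dm)
  inst <- array(0L, dm)
  for (k in seq_len(spec$n_cells)) {
    cl <- cells[[k]]
    ctr <- centres[[k]]
    lobe1 <- ctr + cl$geom$offset * cl$geom$axis_u
    lobe2 <- ctr - cl$geom$offset * cl$geom$axis_u
    a <- cl$geom$elong * cl$geom$lobe_r
    cellmask <- ellipsoid_mask(gc, lobe1, cl$geom$axis_u, a, cl$geom$lobe_r) |
      ellipsoid_mask(gc, lobe2, cl$geom$axis_u, a, cl$geom$lobe_r)
    labels[cellmask] <- 1L
    inst[cellmask] <- k
    placed <- place_organelles(cl$spec, cl$geom, ctr)
    for (p in placed) {
      om <- sphere_mask(gc, p$centre, p$radius)
      labels[om] <- p$class_id
      inst[om] <- k
    }
  }

  mu <- spec$intensity_means[names(sbf_classes)][labels + 1L]
  sdv <- spec$intensity_sds[names(sbf_classes)][labels + 1L]
  vals <- mu + rnorm(length(labels)) * sdv
  if (spec$gain_jitter > 0) {
    gains <- 1 + rnorm(dm[1]) * spec$gain_jitter
    vals <- vals * gains[gc$z]
  }
  vals <- pmin(pmax(round(vals), 0), 255)

  list(raw = raw_volume(array(as.integer(vals), dm), spacing = spec$spacing),
       instances = instance_volume(inst, spacing = spec$spacing),
       labels = label_volume(labels, spacing = spec$spacing))
}

#' Subsample z slices to simulate acquisition anisotropy
#'
#' Keeps every `factor`-th z section of an isotropically generated volume and
#' scales dz accordingly, mimicking the coarser milling step of FIB-SEM
#' acquisition relative to the in-plane pixel size.  The result is the
#' natural input for [correct_anisotropy()].
#'
#' @param volume A [raw_volume()] (or [label_volume()]).
#' @param factor Integer >= 2; the z extent must be divisible by it.
#' @return The subsampled volume with `dz` multiplied by `factor`.
#' @export
degrade_anisotropic <- function(volume, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) stop("factor must be an integer >= 2")
  d <- dim(volume)
  if (d[1] %% factor != 0L)
    stop(sprintf("z extent %d not divisible by factor %d", d[1], factor))
  keep <- seq(1L, d[1], by = factor)
  sp <- volume$spacing
  sp2 <- voxel_spacing(sp[["dz"]] * factor, sp[["dy"]], sp[["dx"]])
  if (inherits(volume, "sbf_labels"))
    label_volume(volume$data[keep, , , drop = FALSE], spacing = sp2)
  else
    raw_volume(volume$data[keep, , , drop = FALSE], spacing = sp2,
               normalized = volume$normalized)
}
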