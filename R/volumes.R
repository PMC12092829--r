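#' @useDynLib sbfseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile sd setNames
#' @importFrom utils head modifyList
"_PACKAGE"

#' Organelle class taxonomy
#'
#' Fixed six-class voxel taxonomy used throughout the package: background,
#' cytoplasm, and the four organelles of a unicellular red alga (one plastid,
#' one mitochondrion, one peroxisome, one nucleus per interphase cell).
#'
#' @format Named integer vector mapping class name to label code 0..5.
#' @export
sbf_classes <- c(
  background    = 0L,
  cytoplasm     = 1L,
  plastid       = 2L,
  mitochondrion = 3L,
  peroxisome    = 4L,
  nucleus       = 5L
)

#' Voxel spacing
#'
#' Physical edge lengths of one voxel along the three volume axes, in
#' nanometres.  Axis order is (z, y, x) with z the milling/acquisition
#' direction.  FIB-SEM stacks are typically anisotropic: the milling step dz
#' differs from the in-plane pixel size.
#'
#' @param dz,dy,dx Positive edge lengths (nm).
#' @return A `voxel_spacing` object (named numeric vector).
#' @export
voxel_spacing <- function(dz, dy, dx) {
  s <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("voxel spacing must be strictly positive and finite")
  structure(s, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing (nm): dz=%g dy=%g dx=%g%s\n",
              x[["dz"]], x[["dy"]], x[["dx"]],
              if (is_isotropic(x)) " [isotropic]" else ""))
  invisible(x)
}

#' Test whether a spacing is isotropic
#' @param spacing A [voxel_spacing()].
#' @param tol Relative tolerance.
#' @return Logical scalar.
#' @export
is_isotropic <- function(spacing, tol = 1e-9) {
  diff(range(spacing)) <= tol * max(spacing)
}

#' Raw intensity volume
#'
#' A serial block-face image: a 3D grid of single-channel intensities indexed
#' `(z, y, x)` (1-based), together with its voxel spacing.  Intensities are
#' either 8-bit values 0..255 (`normalized = FALSE`) or reals in \[0, 1\]
#' (`normalized = TRUE`).  Axis 1 (z) is the milling direction: the volume is
#' the stack of sequential cross-sections.
#'
#' @param data 3D numeric array `(z, y, x)`.
#' @param spacing A [voxel_spacing()].
#' @param normalized Logical; `TRUE` once intensities have been rescaled to
#'   \[0, 1\].
#' @return A `sbf_raw` object.
#' @export
raw_volume <- function(data, spacing = voxel_spacing(1, 1, 1),
                       normalized = FALSE) {
  data <- as_volume_array(data)
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  rng <- range(data)
  if (normalized) {
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized volume must have intensities in [0, 1]")
  } else if (rng[1] < 0 || rng[2] > 255) {
    stop("8-bit volume must have intensities in [0, 255]")
  }
  structure(list(data = data, spacing = spacing, normalized = normalized),
            class = "sbf_raw")
}

#' Label volume
#'
#' Voxel-wise semantic segmentation over the six-class taxonomy of
#' [sbf_classes]: every voxel carries exactly one integer class code 0..5.
#'
#' @param data 3D integer array `(z, y, x)` with values in 0..5.
#' @param spacing A [voxel_spacing()].
#' @return A `sbf_labels` object.
#' @export
label_volume <- function(data, spacing = voxel_spacing(1, 1, 1)) {
  data <- as_volume_array(data, integer = TRUE)
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  if (min(data) < 0L || max(data) > 5L)
    stop("label volume values must lie in 0..5")
  structure(list(data = data, spacing = spacing, class_map = sbf_classes),
            class = "sbf_labels")
}

#' Cell instance volume
#'
#' Voxel-wise instance segmentation of a multi-cell scene: 0 is background,
#' k >= 1 the k-th cell.  Instance identifiers form a contiguous range 1..K.
#'
#' @param data 3D integer array of non-negative instance ids.
#' @param spacing A [voxel_spacing()].
#' @return A `sbf_instances` object.
#' @export
instance_volume <- function(data, spacing = voxel_spacing(1, 1, 1)) {
  data <- as_volume_array(data, integer = TRUE)
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  ids <- sort(unique(as.vector(data)))
  ids <- ids[ids != 0L]
  if (length(ids) && !identical(ids, seq_len(max(ids))))
    stop("instance ids must form a contiguous range 1..K")
  structure(list(data = data, spacing = spacing, n_instances = length(ids)),
            class = "sbf_instances")
}

as_volume_array <- function(data, integer = FALSE) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array indexed (z, y, x)")
  if (length(data) == 0L) stop("volume data must be nonempty")
  if (any(!is.finite(data))) stop("volume data must be finite")
  if (integer) {
    di <- dim(data)
    data <- as.integer(round(data))
    dim(data) <- di
  }
  data
}

#' @export
dim.sbf_raw <- function(x) dim(x$data)
#' @export
dim.sbf_labels <- function(x) dim(x$data)
#' @export
dim.sbf_instances <- function(x) dim(x$data)

#' @export
print.sbf_raw <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("SBF raw volume %d x %d x %d (z,y,x), %s, range [%g, %g]\n",
              d[1], d[2], d[3],
              if (x$normalized) "normalized [0,1]" else "8-bit",
              min(x$data), max(x$data)))
  print(x$spacing)
  invisible(x)
}

#' @export
print.sbf_labels <- function(x, ...) {
  d <- dim(x)
  present <- sort(unique(as.vector(x$data)))
  cat(sprintf("SBF label volume %d x %d x %d (z,y,x); classes present: %s\n",
              d[1], d[2], d[3],
              paste(names(sbf_classes)[match(present, sbf_classes)],
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.sbf_instances <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("SBF instance volume %d x %d x %d (z,y,x); %d cell(s)\n",
              d[1], d[2], d[3], x$n_instances))
  invisible(x)
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("volume shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")))
  invisible(TRUE)
}
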