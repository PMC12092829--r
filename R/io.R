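# Stack I/O: multipage TIFF in (z, y, x) order, one page per cross-section.
# Voxel spacing does not travel in TIFF tags (rarely reliable in FIB-SEM
# exports); it is supplied by the caller or read from a YAML sidecar.

#' Read an image stack as a raw volume
#'
#' Reads either a multipage TIFF or a directory of same-sized single-page
#' TIFF/PNG slices (lexicographic file order = z order) into a [raw_volume()].
#' 8-bit data are preserved bit-exactly.  Inputs deeper than 8 bits are
#' rejected: rescaling is an explicit decision left to the caller.
#'
#' @param path A multipage TIFF file or a directory of single-page slices.
#' @param spacing A [voxel_spacing()]; if `NULL`, a sidecar
#'   `<path>.yaml` written by [write_stack()] is consulted, falling back to
#'   isotropic spacing 1.
#' @return A [raw_volume()] of shape `(n_slices, H, W)`.
#' @export
read_stack <- function(path, spacing = NULL) {
  pages <- read_pages(path)
  vol <- pages_to_array(pages)
  if (is.null(spacing)) spacing <- read_sidecar_spacing(path)
  raw_volume(vol, spacing = spacing, normalized = FALSE)
}

#' Read an image stack as a label volume
#'
#' As [read_stack()], but interprets page values as integer class codes and
#' returns a [label_volume()].
#'
#' @inheritParams read_stack
#' @return A [label_volume()].
#' @export
read_label_stack <- function(path, spacing = NULL) {
  pages <- read_pages(path)
  vol <- pages_to_array(pages)
  if (is.null(spacing)) spacing <- read_sidecar_spacing(path)
  label_volume(vol, spacing = spacing)
}

#' Read an image stack as a cell instance volume
#'
#' @inheritParams read_stack
#' @return An [instance_volume()].
#' @export
read_instance_stack <- function(path, spacing = NULL) {
  pages <- read_pages(path)
  vol <- pages_to_array(pages)
  if (is.null(spacing)) spacing <- read_sidecar_spacing(path)
  instance_volume(vol, spacing = spacing)
}

#' Write a volume as a multipage TIFF
#'
#' Writes one TIFF page per z section.  Raw 8-bit volumes are written as
#' uint8; label and instance volumes as uint8 when all values fit, else
#' uint16.  Normalized raw volumes are quantized back to 8 bits (the on-disk
#' exchange format is integer).  A YAML sidecar `<path>.yaml` records voxel
#' spacing, the volume kind, and the class map for label volumes.
#'
#' @param volume A [raw_volume()], [label_volume()] or [instance_volume()].
#' @param path Output TIFF filename.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, sidecar = TRUE) {
  if (!inherits(volume, c("sbf_raw", "sbf_labels", "sbf_instances")))
    stop("volume must be a raw, label or instance volume")
  v <- volume$data
  if (length(v) == 0L) stop("cannot write an empty volume")
  kind <- class(volume)[1]
  if (kind == "sbf_raw") {
    vals <- if (volume$normalized) round(v * 255) else round(v)
    maxval <- 255
    bits <- 8L
  } else {
    vals <- v
    maxval <- max(v)
    bits <- if (maxval <= 255) 8L else 16L
    maxval <- if (bits == 8L) 255 else 65535
    if (max(v) > 65535) stop("instance/label values exceed uint16 range")
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(seq_len(dim(v)[1]), function(i)
    matrix(vals[i, , ], dim(v)[2], dim(v)[3]) / maxval)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop("cannot write TIFF at ", path,
                                          ": ", conditionMessage(e)))
  if (sidecar) {
    meta <- list(kind = kind,
                 spacing = as.list(unclass(volume$spacing)),
                 bits = bits)
    if (kind == "sbf_labels") meta$class_map <- as.list(sbf_classes)
    if (kind == "sbf_raw") meta$normalized <- FALSE
    yaml::write_yaml(meta, sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

read_sidecar_spacing <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- yaml::read_yaml(sp)
    if (!is.null(meta$spacing))
      return(voxel_spacing(meta$spacing$dz, meta$spacing$dy, meta$spacing$dx))
  }
  voxel_spacing(1, 1, 1)
}

read_pages <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("directory contains no TIFF/PNG slices: ", path)
    lapply(files, read_one_page)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, check_page_depth)
  }
}

read_one_page <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG slices requires the 'png' package")
    p <- png::readPNG(file)
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse grayscale-with-alpha
    matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
  } else {
    check_page_depth(tiff::readTIFF(file, as.is = TRUE))
  }
}

check_page_depth <- function(page) {
  if (length(dim(page)) == 3L) {
    if (dim(page)[3] != 1L)
      stop("multi-channel TIFF pages are not supported (single-channel EM data expected)")
    page <- page[, , 1]
  }
  if (max(page) > 255)
    stop("input deeper than 8 bits; rescale explicitly before reading")
  page
}

pages_to_array <- function(pages) {
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices have inconsistent dimensions")
  n <- length(pages)
  vol <- array(0L, c(n, dims[1, 1], dims[2, 1]))
  for (i in seq_len(n)) vol[i, , ] <- as.integer(pages[[i]])
  vol
}
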