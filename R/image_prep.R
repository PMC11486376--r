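#' Orthographic projection of a 3D volume
#'
#' Collapses a 3D grayscale volume along one anatomical axis into a 2D
#' projection, either by maximum-intensity projection (MIP, the standard 2D
#' rendering for contrast-enhanced breast MRI) or by mean-intensity
#' projection.
#'
#' The axis convention is `sagittal` = dim 1, `coronal` = dim 2,
#' `axial` = dim 3; a bare axis index 1..3 is also accepted.
#'
#' @param vol 3D numeric array of non-negative finite intensities.
#' @param axis `"sagittal"`, `"coronal"`, `"axial"`, or an axis index.
#' @param mode `"max"` (default) or `"mean"`.
#' @return Numeric matrix: the in-plane shape of `vol` perpendicular to
#'   `axis`, with attribute `projection` recording axis and mode.
#' @export
orthographic_project <- function(vol, axis = "sagittal",
                                 mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("`vol` must be a 3D array", call. = FALSE)
  if (any(dim(vol) < 1L) || length(vol) == 0L)
    stop("`vol` must have at least one slice per axis", call. = FALSE)
  if (!all(is.finite(vol)))
    stop("`vol` contains non-finite intensities", call. = FALSE)
  ax_names <- c(sagittal = 1L, coronal = 2L, axial = 3L)
  ax <- if (is.character(axis)) {
    if (!axis %in% names(ax_names))
      stop(sprintf("unknown axis '%s' (expected sagittal/coronal/axial)", axis),
           call. = FALSE)
    ax_names[[axis]]
  } else {
    if (!axis %in% 1:3) stop("axis index must be 1, 2 or 3", call. = FALSE)
    as.integer(axis)
  }
  keep <- setdiff(1:3, ax)
  f <- if (mode == "max") max else mean
  out <- apply(vol, keep, f)
  attr(out, "projection") <- list(axis = ax, mode = mode)
  out
}

#' Nearest-pixel resizing of a 2D image
#'
#' Resizes a square (or rectangular) image to `size x size` by the nearest
#' pixel method: with half-pixel centers, output index `i` (0-based) reads
#' source index `floor((i + 0.5) * src / dst)`. No new intensity values are
#' introduced, and resizing an image to its own size is the identity.
#'
#' @param img numeric matrix.
#' @param size positive integer, the output side length.
#' @return `size x size` numeric matrix.
#' @export
resize_nearest <- function(img, size) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  if (length(size) != 1L || size < 1 || size != round(size))
    stop("`size` must be a positive integer", call. = FALSE)
  size <- as.integer(size)
  map_idx <- function(dst, src) {
    i <- floor((seq_len(dst) - 0.5) * src / dst) + 1L
    pmin(pmax(i, 1L), src)
  }
  img[map_idx(size, nrow(img)), map_idx(size, ncol(img)), drop = FALSE]
}

#' Affine intensity normalization
#'
#' Maps the observed (or fixed) intensity range of an image affinely onto a
#' target interval. Diffusion training uses `[-1, 1]`; metric computation
#' uses `[0, 1]`. A constant image maps to the midpoint of the target range.
#'
#' @param img numeric matrix or array with finite values.
#' @param target_range length-2 numeric, e.g. `c(-1, 1)` or `c(0, 1)`.
#' @param from optional length-2 numeric giving a fixed source range; by
#'   default the observed `range(img)` is used.
#' @return Array shaped like `img` with values inside `target_range`.
#' @export
normalize_range <- function(img, target_range = c(-1, 1), from = NULL) {
  if (!all(is.finite(img))) stop("`img` has non-finite values", call. = FALSE)
  if (length(target_range) != 2L || target_range[1] >= target_range[2])
    stop("`target_range` must be an increasing length-2 interval", call. = FALSE)
  src <- if (is.null(from)) range(img) else from
  if (src[2] - src[1] <= 0) {
    img[] <- mean(target_range)
    return(img)
  }
  out <- (img - src[1]) / (src[2] - src[1])
  out * (target_range[2] - target_range[1]) + target_range[1]
}

#' Read a 3D volume or 2D grayscale image from disk
#'
#' NIfTI volumes (`.nii`, `.nii.gz`) are read with \pkg{RNifti}; PNG and
#' TIFF images with \pkg{png} / \pkg{tiff}. Multi-channel 2D images are
#' collapsed to grayscale by channel averaging.
#'
#' @param path file path.
#' @return 3D array (NIfTI) or matrix (PNG/TIFF).
#' @export
read_volume <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    v <- as.array(RNifti::readNifti(path))
    if (length(dim(v)) > 3L) v <- array(v, dim = dim(v)[1:3])
    return(v)
  }
  img <- if (grepl("\\.png$", lp)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lp)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a 2D grayscale image as PNG
#'
#' Values are clipped to `[0, 1]` before writing (8-bit grayscale). Use the
#' float container ([write_image_float()]) when a lossless round trip is
#' needed.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Lossless float image round-trip
#'
#' Writes/reads an image as a plain-text container (dimensions header plus
#' full-precision values), so preprocessing outputs can be round-tripped
#' exactly in tests and runs.
#'
#' @param img numeric matrix.
#' @param path output path (conventionally `.txt`).
#' @return `read_image_float()` returns the matrix.
#' @export
write_image_float <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(img), ncol(img)), con)
  writeLines(paste(format(as.vector(img), digits = 17), collapse = " "), con)
  invisible(path)
}

#' @rdname write_image_float
#' @export
read_image_float <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- as.numeric(strsplit(lines[2], " +")[[1]])
  matrix(vals, d[1], d[2])
}

#' Full image preprocessing path
#'
#' Convenience wrapper: project a 3D volume (if given), resize to
#' `size x size` by nearest pixel, and normalize to the target range.
#'
#' @param x 3D array or 2D matrix.
#' @param size output side length (default 128, the model's working size).
#' @param axis,mode passed to [orthographic_project()] when `x` is 3D.
#' @param target_range passed to [normalize_range()].
#' @return `size x size` matrix in `target_range`.
#' @export
prepare_image <- function(x, size = 128, axis = "sagittal", mode = "max",
                          target_range = c(-1, 1)) {
  if (is.array(x) && length(dim(x)) == 3L)
    x <- orthographic_project(x, axis = axis, mode = mode)
  attr(x, "projection") <- NULL
  normalize_range(resize_nearest(x, size), target_range)
}
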