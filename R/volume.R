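#' @useDynLib microvessel, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a 3D intensity volume
#'
#' A `volume_image` holds a 3D scalar intensity grid together with its
#' voxel spacing in micrometres. The array axes are (x, y, z), with z the
#' confocal page (slice) axis; physical coordinates follow the
#' voxel-center convention, `coord = (index - 1) * spacing + origin`.
#'
#' @param data 3D numeric array, axes (x, y, z).
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in micrometres;
#'   all components must be positive.
#' @param origin numeric length-3, physical position of voxel (1,1,1) in
#'   micrometres.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (micrometres/voxel)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume_image")
}

#' Construct a binary lumen mask
#'
#' Shares the grid conventions of [volume_image()] but stores logical
#' voxel values (TRUE = lumen).
#'
#' @inheritParams volume_image
#' @param data 3D logical array.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    if (length(setdiff(vals, c(0, 1))) > 0)
      stop("mask data must be logical or 0/1")
    storage.mode(data) <- "logical"
  }
  v <- volume_image(array(FALSE, dim(data)), spacing, origin)
  v$data <- data
  class(v) <- c("binary_mask", "volume_image")
  v
}

#' @exportS3Method base::print
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f um\n",
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  if (inherits(x, "binary_mask")) {
    cat(sprintf("  foreground fraction %.4f\n", mean(x$data)))
  } else {
    cat(sprintf("  intensity range [%g, %g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Read a multipage grayscale TIFF z-stack
#'
#' TIFF page k becomes slice z = k. Voxel spacing must be supplied by the
#' caller: TIFF spatial metadata from microscope exports is unreliable, so
#' it is never trusted. Intensities are read bit-exactly (integer sample
#' values are preserved).
#'
#' @param path path to a multipage grayscale TIFF.
#' @param spacing voxel size (dx, dy, dz) in micrometres.
#' @return A [volume_image()].
#' @export
read_stack <- function(path, spacing) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("non-grayscale page in ", path, " (expected single channel)")
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  # readTIFF returns [row, col] = [y, x]; transpose to data[x, y]
  arr <- array(0, c(shp[2], shp[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  volume_image(arr, spacing)
}

#' Write a volume as a multipage grayscale TIFF
#'
#' Integer intensities in `[0, 2^bits - 1]` round-trip exactly through
#' [read_stack()].
#'
#' @param img a [volume_image()] or [binary_mask()] (written as 0/255
#'   equivalent full-scale values).
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_stack <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "volume_image"))
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  scale <- 2^bits - 1
  data <- img$data
  if (is.logical(data)) data <- data * scale
  if (min(data) < 0 || max(data) > scale)
    stop("intensities outside [0, ", scale, "]; rescale before writing")
  pages <- lapply(seq_len(dim(data)[3]),
                  function(k) t(data[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

#' Resample an anisotropic stack to cubic voxels
#'
#' Confocal stacks typically have a z step several times the in-plane
#' pixel size. Linear interpolation along z resamples the volume onto a
#' cubic grid with spacing equal to the x-y pixel size; x-y planes are
#' untouched and the physical z extent is preserved to within one voxel.
#'
#' @param img a [volume_image()] with `dx == dy` and `dz >= dx`.
#' @return A [volume_image()] with spacing `(dx, dx, dx)`. Already-cubic
#'   input is returned unchanged.
#' @export
isotropize <- function(img) {
  stopifnot(inherits(img, "volume_image"))
  sp <- img$spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * sp[1])
    stop("anisotropic x-y pixels are unsupported (dx must equal dy)")
  if (sp[3] < sp[1] - 1e-9 * sp[1])
    stop("dz must be >= dx")
  if (abs(sp[3] - sp[1]) <= 1e-9 * sp[1]) return(img)
  d <- dim(img$data)
  nz_new <- round((d[3] - 1) * sp[3] / sp[1]) + 1
  out <- array(0, c(d[1], d[2], nz_new))
  for (k in seq_len(nz_new)) {
    zpos <- (k - 1) * sp[1] / sp[3]          # in input slice units (0-based)
    k0 <- floor(zpos)
    w <- zpos - k0
    k0 <- min(k0, d[3] - 1)                  # clamp at the top slice
    if (k0 == d[3] - 1) { k0 <- d[3] - 2; w <- 1 }
    if (d[3] == 1) { out[, , k] <- img$data[, , 1]; next }
    out[, , k] <- (1 - w) * img$data[, , k0 + 1] + w * img$data[, , k0 + 2]
  }
  res <- volume_image(out, c(sp[1], sp[1], sp[1]), img$origin)
  if (inherits(img, "binary_mask")) res <- binary_mask(out >= 0.5, res$spacing)
  res
}

#' Downsample a volume by integer decimation
#'
#' Keeps one voxel out of `n` along each axis (pure decimation, no
#' smoothing): output voxel (i, j, k) equals input voxel
#' (n(i-1)+1, n(j-1)+1, n(k-1)+1) and the spacing is multiplied by `n`.
#'
#' @param img a [volume_image()] or [binary_mask()].
#' @param n positive integer decimation factor; every axis must be at
#'   least `n` voxels long.
#' @export
downsample <- function(img, n) {
  stopifnot(inherits(img, "volume_image"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  d <- dim(img$data)
  if (any(d < n)) stop("downsampling factor ", n, " exceeds an axis length")
  if (n == 1L) return(img)
  out <- img$data[seq(1, d[1], by = n),
                  seq(1, d[2], by = n),
                  seq(1, d[3], by = n), drop = FALSE]
  if (inherits(img, "binary_mask"))
    binary_mask(out, img$spacing * n, img$origin)
  else
    volume_image(out, img$spacing * n, img$origin)
}

# voxel-center physical coordinates of array indices (1-based)
voxel_coords <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}
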