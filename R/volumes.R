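#' Volumetric image with physical voxel spacing
#'
#' Light containers for a 3D scalar grid (`vol_image`) and a binary mask on
#' the same grid (`vol_mask`). Spacing is in millimetres per voxel along
#' (x, y, z).
#'
#' @param data 3D numeric array (image) or logical/0-1 array (mask).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `vol_image` or `vol_mask`.
#' @export
vol_image <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("image data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "vol_image")
}

#' @rdname vol_image
#' @export
vol_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("mask data must be a 3D array")
  d <- data
  if (!is.logical(d)) {
    if (!all(d %in% c(0, 1))) stopf("mask values must be 0/1 or logical")
    d <- array(d != 0, dim = dim(d))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  structure(list(data = d, spacing = spacing), class = "vol_mask")
}

#' @export
print.vol_image <- function(x, ...) {
  cat(sprintf("<vol_image> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.vol_mask <- function(x, ...) {
  cat(sprintf("<vol_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

is_isotropic <- function(spacing, tol = 1e-6) {
  diff(range(spacing)) <= tol * max(spacing)
}

#' Read / write volumes as NIfTI
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param x A `vol_image` or `vol_mask`.
#' @param mask Logical; read as a binary mask?
#' @return `read_volume()` returns a `vol_image` or `vol_mask`;
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  sp <- RNifti::pixdim(nim)[1:3]
  if (mask) vol_mask(array(arr != 0, dim = dim(arr)), sp)
  else vol_image(arr, sp)
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("vol_image", "vol_mask")))
  arr <- if (inherits(x, "vol_mask")) array(as.integer(x$data), dim = dim(x$data)) else x$data
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- x$spacing
  RNifti::writeNifti(nim, path)
  invisible(path)
}

# Trilinear interpolation of a 3D array at continuous (1-based) voxel
# coordinates, clamped to the array boundary.
interp_trilinear <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  ix <- cl(ix, d[1]); iy <- cl(iy, d[2]); iz <- cl(iz, d[3])
  x0 <- pmin(floor(ix), d[1] - 1L); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(iy), d[2] - 1L); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(iz), d[3] - 1L); z0 <- pmax(z0, 1)
  if (d[1] == 1L) x0 <- rep(1, length(ix))
  if (d[2] == 1L) y0 <- rep(1, length(iy))
  if (d[3] == 1L) z0 <- rep(1, length(iz))
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(xi, yi, zi) arr[cbind(xi, yi, zi)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}
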