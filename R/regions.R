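#' Region-construction configuration
#'
#' Parameters for building the intratumoral/peritumoral region pair: the
#' peritumoral annulus thickness (4 mm primary, 8 mm for margin-sensitivity
#' analysis) and the isotropic resampling target applied before feature
#' extraction.
#'
#' @param margin_mm Positive annulus thickness in mm (default 4).
#' @param target_spacing_mm Isotropic resample spacing in mm (default 1).
#' @return A `region_config` list.
#' @export
region_config <- function(margin_mm = 4, target_spacing_mm = 1) {
  if (!is_scalar_num(margin_mm) || margin_mm <= 0)
    stopf("margin_mm must be a positive number")
  if (!is_scalar_num(target_spacing_mm) || target_spacing_mm <= 0)
    stopf("target_spacing_mm must be a positive number")
  structure(list(margin_mm = margin_mm,
                 target_spacing_mm = target_spacing_mm,
                 image_interpolation = "linear",
                 mask_interpolation = "nearest"),
            class = "region_config")
}

#' Resample an image/mask pair to an isotropic grid
#'
#' Trilinear interpolation for the image, nearest-neighbour for the mask (so
#' the mask stays binary). Output voxel centres tile the same physical extent
#' at `target_spacing_mm` in all three axes.
#'
#' @param image A `vol_image`.
#' @param mask A `vol_mask` on the same grid.
#' @param config A [region_config()].
#' @return List with elements `image` and `mask` on the isotropic grid.
#' @export
resample_isotropic <- function(image, mask, config = region_config()) {
  stopifnot(inherits(image, "vol_image"), inherits(mask, "vol_mask"))
  if (!identical(dim(image$data), dim(mask$data)) ||
      max(abs(image$spacing - mask$spacing)) > 1e-9)
    stopf("image and mask must share a grid")
  if (!any(mask$data)) stopf("mask is empty")
  if (any(!is.finite(image$data))) stopf("image contains non-finite voxels")
  t <- config$target_spacing_mm
  d <- dim(image$data)
  s <- image$spacing
  nd <- pmax(1L, as.integer(round(d * s / t)))
  # output voxel centre j -> physical (j - 0.5) * t -> input index phys/s + 0.5
  idx <- lapply(1:3, function(a) ((seq_len(nd[a]) - 0.5) * t) / s[a] + 0.5)
  ix <- rep(idx[[1]], times = nd[2] * nd[3])
  iy <- rep(rep(idx[[2]], each = nd[1]), times = nd[3])
  iz <- rep(idx[[3]], each = nd[1] * nd[2])
  img_out <- array(interp_trilinear(image$data, ix, iy, iz), dim = nd)
  cl <- function(v, n) pmin(pmax(round(v), 1), n)
  msk_out <- array(mask$data[cbind(cl(ix, d[1]), cl(iy, d[2]), cl(iz, d[3]))],
                   dim = nd)
  if (!any(msk_out)) stopf("mask vanished under resampling (lesion below grid resolution)")
  list(image = vol_image(img_out, rep(t, 3)),
       mask = vol_mask(msk_out, rep(t, 3)))
}

#' Physical-distance dilation of a binary mask
#'
#' Grows the mask to all voxels whose centre-to-centre Euclidean distance (in
#' mm) to the nearest foreground voxel is at most `margin_mm`, using an exact
#' squared Euclidean distance transform.
#'
#' @param mask A `vol_mask` on an isotropic grid.
#' @param margin_mm Positive margin in mm.
#' @return A `vol_mask` that is a superset of the input.
#' @export
dilate_physical <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "vol_mask"))
  if (!is_scalar_num(margin_mm) || margin_mm <= 0)
    stopf("margin_mm must be positive")
  if (!is_isotropic(mask$spacing))
    stopf("dilate_physical requires an isotropic grid; resample first")
  if (!any(mask$data)) stopf("mask is empty")
  d2 <- .edt_sq(as.vector(mask$data), dim(mask$data), mask$spacing)
  out <- array(d2 <= margin_mm^2 * (1 + 1e-9), dim = dim(mask$data))
  vol_mask(out, mask$spacing)
}

#' Build intratumoral, peritumoral and combined regions
#'
#' The peritumoral annulus is the physical dilation of the tumor mask minus
#' the tumor itself, clipped to the image bounds; the combined region is their
#' union (equivalently, the dilated mask).
#'
#' @param mask A `vol_mask` (tumor) on an isotropic grid.
#' @param config A [region_config()].
#' @return A `region_set` with `intratumoral`, `peritumoral`, `combined`
#'   masks and the common `spacing`.
#' @export
build_regions <- function(mask, config = region_config()) {
  dil <- dilate_physical(mask, config$margin_mm)
  peri <- array(dil$data & !mask$data, dim = dim(mask$data))
  if (!any(peri)) stopf("peritumoral annulus is empty after clipping")
  structure(list(intratumoral = mask,
                 peritumoral = vol_mask(peri, mask$spacing),
                 combined = dil,
                 spacing = mask$spacing,
                 margin_mm = config$margin_mm),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> margin %g mm: tumor %d vx, annulus %d vx, combined %d vx\n",
              x$margin_mm, sum(x$intratumoral$data), sum(x$peritumoral$data),
              sum(x$combined$data)))
  invisible(x)
}

#' Segmentation overlap coefficients
#'
#' Dice similarity coefficient `2|A∩B|/(|A|+|B|)` and Jaccard coefficient
#' `|A∩B|/|A∪B|` between two masks on the same grid.
#'
#' @param a,b `vol_mask` objects on identical grids.
#' @return A fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  ab <- overlap_counts(a, b)
  2 * ab$inter / (ab$na + ab$nb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  ab <- overlap_counts(a, b)
  ab$inter / (ab$na + ab$nb - ab$inter)
}

overlap_counts <- function(a, b) {
  stopifnot(inherits(a, "vol_mask"), inherits(b, "vol_mask"))
  if (!identical(dim(a$data), dim(b$data)))
    stopf("masks must share a grid")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) stopf("both masks are empty")
  list(inter = sum(a$data & b$data), na = na, nb = nb)
}

#' Segmentation-reproducibility report
#'
#' Given two matched sets of segmentations of the same cases (e.g. original
#' and repeat segmentations by the same reader), reports per-case Dice and
#' Jaccard coefficients with their means and standard deviations.
#'
#' @param masks_a,masks_b Lists of `vol_mask` objects, matched by position.
#' @return A list with a per-case `table` (data.frame) and `summary`
#'   (mean/SD of DSC and JSC).
#' @export
overlap_report <- function(masks_a, masks_b) {
  if (length(masks_a) != length(masks_b))
    stopf("mask sets must have equal length")
  dsc <- mapply(dice, masks_a, masks_b)
  jsc <- mapply(jaccard, masks_a, masks_b)
  list(table = data.frame(case = seq_along(dsc), dsc = dsc, jsc = jsc),
       summary = c(dsc_mean = mean(dsc), dsc_sd = sd(dsc),
                   jsc_mean = mean(jsc), jsc_sd = sd(jsc)))
}
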