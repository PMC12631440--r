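#' 162-feature texture block
#'
#' GLCM and GLRLM matrices are computed per direction over the 13 unique 3D
#' offsets at one-voxel distance; the 26 GLCM descriptors are aggregated over
#' directions by Mean/Std/Min/Max/Range (130 features) and the 16 GLRLM
#' descriptors by Mean/Std (32 features). Aggregation Std is the sample
#' standard deviation across the 13 per-direction values.
#'
#' @param values Numeric vector of in-region intensities.
#' @param mask_arr Logical 3D array locating `values` on the grid.
#' @param config A [discretization_config()].
#' @return Named numeric vector of length 162.
#' @export
texture_block <- function(values, mask_arr, config = discretization_config()) {
  stopifnot(sum(mask_arr) == length(values))
  larr <- array(NA_integer_, dim = dim(mask_arr))
  larr[mask_arr] <- discretize(values, config)
  offs <- offsets_13()
  ng <- config$n_bins
  nvox <- length(values)
  gl <- matrix(NA_real_, length(GLCM_NAMES), nrow(offs),
               dimnames = list(GLCM_NAMES, NULL))
  rl <- matrix(NA_real_, length(GLRLM_NAMES), nrow(offs),
               dimnames = list(GLRLM_NAMES, NULL))
  for (k in seq_len(nrow(offs))) {
    gl[, k] <- glcm_descriptors(glcm(larr, offs[k, ], ng))
    rl[, k] <- glrlm_descriptors(glrlm(larr, offs[k, ], ng), nvox)
  }
  agg <- function(x, stat) {
    switch(stat,
           Mean = rowMeans(x),
           Std = apply(x, 1, sd),
           Min = apply(x, 1, min),
           Max = apply(x, 1, max),
           Range = apply(x, 1, max) - apply(x, 1, min))
  }
  out <- numeric(0)
  for (nm in GLCM_NAMES)
    for (st in GLCM_AGG)
      out[paste0("glcm_", nm, "_", st)] <- agg(gl[nm, , drop = FALSE], st)
  for (nm in GLRLM_NAMES)
    for (st in GLRLM_AGG)
      out[paste0("glrlm_", nm, "_", st)] <- agg(rl[nm, , drop = FALSE], st)
  out
}

crop_to_mask <- function(arr, mask_arr, pad = 1L) {
  idx <- which(mask_arr, arr.ind = TRUE)
  d <- dim(mask_arr)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  list(arr = arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

#' Extract the full feature vector for one region
#'
#' Computes every feature in the registry for one image/region pair on the
#' isotropic grid: first-order and texture features from the original image,
#' shape features once from the mask, and first-order + texture features from
#' each of the 8 Haar sub-bands. Any non-finite feature value (a degenerate
#' descriptor on a pathological region) raises an error naming the feature.
#'
#' @param image A `vol_image` on an isotropic grid.
#' @param mask A `vol_mask` delimiting the region, on the same grid.
#' @param registry Feature registry (default [default_registry()]).
#' @param config A [discretization_config()].
#' @return Named numeric vector with one finite value per registry entry.
#' @export
extract_all <- function(image, mask, registry = default_registry(),
                        config = discretization_config()) {
  stopifnot(inherits(image, "vol_image"), inherits(mask, "vol_mask"))
  if (!identical(dim(image$data), dim(mask$data)))
    stopf("image and mask must share a grid")
  if (!is_isotropic(image$spacing))
    stopf("extract_all expects an isotropic grid; resample first")
  if (!any(mask$data)) stopf("mask is empty")
  cr <- crop_to_mask(image$data, mask$data, pad = 2L)
  arr <- cr$arr; msk <- cr$mask
  vals <- arr[msk]
  out <- c(first_order(vals, config),
           shape_features(vol_mask(msk, mask$spacing)),
           texture_block(vals, msk, config))
  sbs <- wavelet_subbands(arr)
  for (sb in WAVELET_SUBBANDS) {
    v <- sbs[[sb]][msk]
    blk <- c(first_order(v, config), texture_block(v, msk, config))
    names(blk) <- paste0("wavelet_", sb, "_", names(blk))
    out <- c(out, blk)
  }
  out <- out[registry$name]
  names(out) <- registry$name
  bad <- !is.finite(out)
  if (any(bad))
    stopf("non-finite feature value(s): %s",
          paste(head(registry$name[bad], 5), collapse = ", "))
  out
}

#' Extract features for every case of a cohort
#'
#' Runs resampling, region construction and [extract_all()] for each case and
#' requested sequence, returning one feature table per (sequence, region)
#' combination. Region `intratumoral` uses the tumor mask, `combined` the
#' union of tumor and peritumoral annulus.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param sequences Character vector of sequence tags (default: all five).
#' @param region_cfg A [region_config()].
#' @param disc_cfg A [discretization_config()].
#' @param registry Feature registry.
#' @param verbose Print progress?
#' @return Named list `tables[[sequence]][[region]]` of numeric matrices
#'   (cases x 1618 features).
#' @export
extract_cohort <- function(cohort, sequences = NULL,
                           region_cfg = region_config(),
                           disc_cfg = discretization_config(),
                           registry = default_registry(),
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "tme_cohort"))
  if (is.null(sequences)) sequences <- names(cohort$config$sequences)
  n <- cohort$config$n_cases
  tables <- list()
  for (sq in sequences)
    tables[[sq]] <- list(
      intratumoral = matrix(NA_real_, n, nrow(registry),
                            dimnames = list(NULL, registry$name)),
      combined = matrix(NA_real_, n, nrow(registry),
                        dimnames = list(NULL, registry$name)))
  for (i in seq_len(n)) {
    case <- generate_case(cohort, i, sequences = sequences)
    for (sq in sequences) {
      iso <- resample_isotropic(case$images[[sq]], case$masks[[sq]], region_cfg)
      regs <- build_regions(iso$mask, region_cfg)
      tables[[sq]]$intratumoral[i, ] <-
        extract_all(iso$image, regs$intratumoral, registry, disc_cfg)
      tables[[sq]]$combined[i, ] <-
        extract_all(iso$image, regs$combined, registry, disc_cfg)
    }
    if (verbose && i %% 10 == 0) message("extracted case ", i, "/", n)
  }
  tables
}
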