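# Single-level undecimated (stationary) Haar decomposition. Sub-bands keep
# the input grid, so the tumor mask applies to every sub-band directly, and
# the transform inverts exactly: x[i] = (L[i] + H[i]) / sqrt(2) per axis.

haar_axis <- function(arr, axis, kind) {
  d <- dim(arr)
  idx <- seq_len(d[axis])
  nxt <- c(idx[-1], idx[1])  # circular boundary
  pick <- function(which_idx) {
    sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel[[axis]] <- which_idx
    do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
  }
  a <- pick(idx)
  b <- pick(nxt)
  if (kind == "L") (a + b) / sqrt(2) else (a - b) / sqrt(2)
}

#' Single-level 3D Haar wavelet sub-bands
#'
#' Undecimated separable Haar decomposition along the three axes, giving the
#' eight sub-bands `LLL`..`HHH` (letter k is the filter applied along axis k)
#' on the same grid as the input, with circular boundary handling.
#'
#' @param image A `vol_image` (or bare 3D array) on an isotropic grid.
#' @return Named list of eight 3D arrays.
#' @export
wavelet_subbands <- function(image) {
  arr <- if (inherits(image, "vol_image")) image$data else image
  if (!is.array(arr) || length(dim(arr)) != 3L) stopf("need a 3D array")
  if (any(dim(arr) < 2L)) stopf("region smaller than the Haar filter support")
  out <- list()
  for (sb in WAVELET_SUBBANDS) {
    f <- strsplit(sb, "")[[1]]
    a <- haar_axis(arr, 1L, f[1])
    a <- haar_axis(a, 2L, f[2])
    a <- haar_axis(a, 3L, f[3])
    out[[sb]] <- a
  }
  out
}

#' Invert the single-level Haar decomposition
#'
#' Exact inverse of [wavelet_subbands()]; used to verify perfect
#' reconstruction.
#'
#' @param subbands Named list of eight arrays from [wavelet_subbands()].
#' @return The reconstructed 3D array.
#' @export
wavelet_reconstruct <- function(subbands) {
  stopifnot(all(WAVELET_SUBBANDS %in% names(subbands)))
  # invert axis 3: L3 = (A + B)/s, H3 = (A - B)/s  =>  A = (L3 + H3)/s at i
  inv <- function(l, h) (l + h) / sqrt(2)
  ll <- inv(subbands$LLL, subbands$LLH)
  lh <- inv(subbands$LHL, subbands$LHH)
  hl <- inv(subbands$HLL, subbands$HLH)
  hh <- inv(subbands$HHL, subbands$HHH)
  l <- inv(ll, lh)
  h <- inv(hl, hh)
  inv(l, h)
}
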