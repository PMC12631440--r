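#' Gray-level run-length matrix
#'
#' Runs are maximal collinear segments of constant gray level lying entirely
#' inside the mask, along one of the 13 unique 3D directions. The matrix is
#' indexed (gray level, run length).
#'
#' @param larr 3D integer array of gray levels with `NA` outside the mask.
#' @param offset Integer length-3 direction (one of [offsets_13()]).
#' @param n_levels Number of gray levels.
#' @return An `n_levels` x `max_run` count matrix.
#' @export
glrlm <- function(larr, offset, n_levels) {
  d <- dim(larr)
  N <- prod(d)
  if (sum(!is.na(larr)) < 1L) stopf("empty region")
  ii <- seq_len(N) - 1L
  x <- ii %% d[1] + 1L
  y <- (ii %/% d[1]) %% d[2] + 1L
  z <- ii %/% (d[1] * d[2]) + 1L
  # steps backwards along -offset until the grid boundary
  back <- rep(.Machine$integer.max, N)
  crd <- list(x, y, z)
  for (a in 1:3) {
    o <- offset[a]
    if (o == 1L) back <- pmin(back, crd[[a]] - 1L)
    else if (o == -1L) back <- pmin(back, d[a] - crd[[a]])
  }
  sx <- x - back * offset[1]
  sy <- y - back * offset[2]
  sz <- z - back * offset[3]
  key <- (sz - 1) * (d[1] * d[2]) + (sy - 1) * d[1] + sx  # line id
  ord <- order(key, back)
  kk <- key[ord]
  lv <- as.vector(larr)[ord]
  # run boundaries: new line, level change, or NA gap
  n <- length(lv)
  new_run <- c(TRUE, kk[-1] != kk[-n] | is.na(lv[-1]) | is.na(lv[-n]) |
                 lv[-1] != lv[-n])
  new_run[is.na(new_run)] <- TRUE
  run_id <- cumsum(new_run)
  keep <- !is.na(lv)
  if (!any(keep)) stopf("empty region")
  rid <- run_id[keep]
  rlev <- lv[keep]
  len <- tabulate(rid)
  first <- which(!duplicated(rid))
  run_len <- len[rid[first]]
  run_lev <- rlev[first]
  maxr <- max(run_len)
  m <- matrix(0, n_levels, maxr)
  tab <- tabulate((run_lev - 1L) * maxr + run_len, nbins = n_levels * maxr)
  matrix(tab, n_levels, maxr, byrow = TRUE)
}

#' GLRLM descriptors
#'
#' The 16 classical run-length statistics (short/long-run emphases,
#' gray-level and run-length non-uniformities and their normalized variants,
#' run percentage, gray-level and run-length variances, run entropy, and the
#' four joint low/high gray-level emphases).
#'
#' @param R Run-length count matrix from [glrlm()].
#' @param n_voxels Number of voxels in the region (for RunPercentage).
#' @return Named numeric vector of length 16.
#' @export
glrlm_descriptors <- function(R, n_voxels) {
  nr <- sum(R)
  if (nr < 1) stopf("no runs")
  i <- row(R); j <- col(R)
  p <- R / nr
  g <- rowSums(R); r <- colSums(R)
  jl <- seq_len(ncol(R))
  il <- seq_len(nrow(R))
  mu_g <- sum(il * g / nr)
  mu_r <- sum(jl * r / nr)
  pe <- p[p > 0]
  c(ShortRunEmphasis = sum(r / jl^2) / nr,
    LongRunEmphasis = sum(r * jl^2) / nr,
    GrayLevelNonUniformity = sum(g^2) / nr,
    GrayLevelNonUniformityNormalized = sum(g^2) / nr^2,
    RunLengthNonUniformity = sum(r^2) / nr,
    RunLengthNonUniformityNormalized = sum(r^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum((i - mu_g)^2 * p),
    RunVariance = sum((j - mu_r)^2 * p),
    RunEntropy = -sum(pe * log2(pe)),
    LowGrayLevelRunEmphasis = sum(g / il^2) / nr,
    HighGrayLevelRunEmphasis = sum(g * il^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * j^2) / nr)
}
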