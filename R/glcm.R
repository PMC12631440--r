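#' The 13 unique 3D direction offsets
#'
#' Integer offset vectors covering all 26-connected neighbour directions up to
#' sign, at an offset distance of one voxel on the isotropic grid.
#'
#' @return A 13 x 3 integer matrix.
#' @export
offsets_13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Extract aligned (A, B) level pairs for one offset; NA marks out-of-mask.
shifted_pairs <- function(larr, off) {
  d <- dim(larr)
  rng <- function(n, o) if (o >= 0) seq_len(n - o) else seq.int(1 - o, n)
  xs <- rng(d[1], off[1]); ys <- rng(d[2], off[2]); zs <- rng(d[3], off[3])
  a <- larr[xs, ys, zs, drop = FALSE]
  b <- larr[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalized co-occurrence matrix of discretized gray levels for
#' one direction offset: each in-mask voxel pair at the given offset is
#' counted in both orders and the matrix is normalized to sum 1.
#'
#' @param larr 3D integer array of gray levels with `NA` outside the mask.
#' @param offset Integer length-3 offset (one of [offsets_13()]).
#' @param n_levels Number of gray levels.
#' @return An `n_levels` x `n_levels` matrix summing to 1.
#' @export
glcm <- function(larr, offset, n_levels) {
  p <- shifted_pairs(larr, offset)
  if (length(p$a) < 1L) stopf("no valid voxel pair for offset (%s)",
                              paste(offset, collapse = ","))
  counts <- tabulate((p$a - 1L) * n_levels + p$b, nbins = n_levels^2)
  m <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

#' GLCM descriptors
#'
#' The 26 co-occurrence descriptors: the 24 classical joint-matrix statistics
#' plus Dissimilarity and SumVariance. Descriptors that are undefined on a
#' degenerate matrix (single occupied gray level: Correlation, Imc1, Imc2,
#' MCC) return `NaN`; [extract_all()] turns any non-finite feature into an
#' error naming it.
#'
#' @param P Normalized symmetric co-occurrence matrix from [glcm()].
#' @return Named numeric vector of length 26.
#' @export
glcm_descriptors <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  # diagonal / cross-diagonal distributions
  kd <- 0:(ng - 1)
  pd <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  ps <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum(kd * pd)
  sa <- sum(ks * ps)
  hxy <- ent(P)
  hx <- ent(px)
  pxy_prod <- outer(px, px)
  pos <- P > 0 & pxy_prod > 0
  hxy1 <- -sum(P[pos] * log2(pxy_prod[pos]))
  pp <- pxy_prod[pxy_prod > 0]
  hxy2 <- -sum(pp * log2(pp))
  nz <- which(px > 0)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else NaN
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NaN
  imc2 <- if (length(nz) > 1L) sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))) else NaN
  mcc <- NaN
  if (length(nz) > 1L) {
    Pn <- P[nz, nz, drop = FALSE]
    pxn <- px[nz]
    # Q(a,b) = sum_k P(a,k) P(b,k) / (px(a) px(k))
    W <- sweep(Pn, 2, pxn, "/")
    Q <- sweep(Pn %*% t(W), 1, pxn, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(0, ev[2]))
  }
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sa,
    SumEntropy = ent(ps),
    SumSquares = sig2,
    Dissimilarity = sum(abs(i - j) * P),
    SumVariance = sum((ks - sa)^2 * ps))
}
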