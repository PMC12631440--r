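# Independent brute-force oracles used to validate the implementation paths.

# ball-shaped mask on an isotropic grid
make_ball_mask <- function(r_vox, n, spacing = 1) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  arr <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r_vox^2,
               c(n, n, n))
  vol_mask(arr, rep(spacing, 3))
}

random_mask <- function(dims, n_fg, seed) {
  set.seed(seed)
  arr <- array(FALSE, dims)
  arr[sample(prod(dims), n_fg)] <- TRUE
  arr
}

# exhaustive nearest-foreground dilation: voxel kept iff its centre lies
# within margin of some foreground centre
brute_dilate <- function(mask_arr, spacing, margin) {
  d <- dim(mask_arr)
  fg <- which(mask_arr, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (k in seq_len(nrow(all_idx))) {
    dx <- (all_idx[k, 1] - fg[, 1]) * spacing[1]
    dy <- (all_idx[k, 2] - fg[, 2]) * spacing[2]
    dz <- (all_idx[k, 3] - fg[, 3]) * spacing[3]
    out[all_idx[k, 1], all_idx[k, 2], all_idx[k, 3]] <-
      min(dx^2 + dy^2 + dz^2) <= margin^2 + 1e-9
  }
  out
}

# exhaustive pair-enumeration GLCM
glcm_oracle <- function(larr, off, n_levels) {
  d <- dim(larr)
  m <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- larr[x, y, z]
    if (is.na(a)) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    b <- larr[x2, y2, z2]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m / sum(m)
}

# exhaustive run-scanner GLRLM
glrlm_oracle <- function(larr, off, n_levels) {
  d <- dim(larr)
  inb <- function(p) all(p >= 1) && all(p <= d)
  runs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    v <- larr[x, y, z]
    if (is.na(v)) next
    prev <- p - off
    # run start: predecessor out of grid, out of mask, or different level
    if (inb(prev) && !is.na(larr[prev[1], prev[2], prev[3]]) &&
        larr[prev[1], prev[2], prev[3]] == v) next
    len <- 1
    q <- p + off
    while (inb(q) && !is.na(larr[q[1], q[2], q[3]]) &&
           larr[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  rr <- do.call(rbind, runs)
  maxr <- max(rr[, 2])
  m <- matrix(0, n_levels, maxr)
  for (k in seq_len(nrow(rr))) m[rr[k, 1], rr[k, 2]] <- m[rr[k, 1], rr[k, 2]] + 1
  m
}

# exact pair-counting AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

random_levels_array <- function(dims, n_levels, p_mask = 0.8, seed = 1) {
  set.seed(seed)
  arr <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  arr[array(runif(prod(dims)) > p_mask, dims)] <- NA_integer_
  if (all(is.na(arr))) arr[1, 1, 1] <- 1L
  arr
}
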