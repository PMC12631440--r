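test_that("default registry realizes the printed feature taxonomy", {
  reg <- default_registry()
  cnt <- registry_counts(reg)
  expect_identical(cnt[["first_order"]], 17L)
  expect_identical(cnt[["shape"]], 7L)
  expect_identical(cnt[["texture"]], 162L)
  expect_identical(cnt[["wavelet"]], 1432L)
  expect_identical(cnt[["total"]], 1618L)
  expect_identical(cnt[["wavelet"]], 8L * (17L + 162L))
  expect_false(anyDuplicated(reg$name) > 0)
  # the published signature names must be representable
  expect_true(all(c("first_order_Mean", "first_order_Skewness",
                    "first_order_StandardDeviation", "first_order_Kurtosis",
                    "first_order_Range", "first_order_Sum",
                    "first_order_Energy", "first_order_Median",
                    "shape_Sphericity") %in% reg$name))
  expect_true(any(grepl("^glcm_Contrast_", reg$name)))
  expect_true("glcm_JointEntropy_Std" %in% reg$name)
  expect_true("glcm_ClusterShade_Mean" %in% reg$name)
})

test_that("discretization forces equal-width levels", {
  expect_identical(discretize(c(0, 1, 2, 3), discretization_config(4)),
                   1:4)
  expect_identical(discretize(rep(7, 5)), rep(1L, 5))
  # monotone transform preserves rank order of levels
  v <- rnorm(50)
  l1 <- discretize(v, discretization_config(8))
  l2 <- discretize(exp(v), discretization_config(8))
  expect_true(all(diff(l1[order(v)]) >= 0))
  expect_true(all(diff(l2[order(v)]) >= 0))
})

test_that("first-order statistics match hand formulas and known moments", {
  f <- first_order(c(1, 2, 3, 4))
  expect_equal(f[["first_order_Mean"]], 2.5)
  expect_equal(f[["first_order_Sum"]], 10)
  expect_equal(f[["first_order_Range"]], 3)
  expect_equal(f[["first_order_Energy"]], 30)
  expect_equal(f[["first_order_Median"]], 2.5)
  expect_equal(f[["first_order_StandardDeviation"]],
               sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  # symmetric sample has zero skewness
  expect_equal(first_order(c(-2, -1, 0, 1, 2))[["first_order_Skewness"]], 0)
  # population moments of a standard normal sample within 3 SE
  set.seed(42)
  x <- rnorm(1000)
  f2 <- first_order(x)
  expect_lt(abs(f2[["first_order_StandardDeviation"]] - 1), 3 / sqrt(2 * 1000))
  expect_lt(abs(f2[["first_order_Skewness"]]), 3 * sqrt(6 / 1000))
  expect_lt(abs(f2[["first_order_Kurtosis"]]), 3 * sqrt(24 / 1000))
  expect_error(first_order(numeric(0)))
  expect_error(first_order(3))
})

test_that("glcm matches hand-enumerated worked examples", {
  larr <- array(NA_integer_, c(2, 2, 1))
  larr[1, , 1] <- c(1L, 1L)  # first row 1 1
  larr[2, , 1] <- c(2L, 2L)  # second row 2 2
  # along-row offset: pairs (1,1) and (2,2)
  P <- glcm(larr, c(0, 1, 0), 2)
  expect_equal(P, diag(0.5, 2))
  dh <- glcm_descriptors(P)
  expect_equal(dh[["Contrast"]], 0)
  expect_equal(dh[["JointEntropy"]], 1)  # 1 bit
  # across-row offset: all mass on (1,2)/(2,1)
  P2 <- glcm(larr, c(1, 0, 0), 2)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(glcm_descriptors(P2)[["Contrast"]], 1)
})

test_that("glcm equals the exhaustive-enumeration oracle on small grids", {
  offs <- offsets_13()
  for (s in 1:12) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:5, 1)
    larr <- random_levels_array(dims, ng, p_mask = 0.8, seed = s)
    for (k in seq_len(nrow(offs))) {
      want <- try(glcm_oracle(larr, offs[k, ], ng), silent = TRUE)
      if (inherits(want, "try-error") || any(!is.finite(want))) {
        expect_error(glcm(larr, offs[k, ], ng))
      } else {
        expect_equal(glcm(larr, offs[k, ], ng), want,
                     label = sprintf("seed %d offset %d", s, k))
      }
    }
  }
  # normalization and symmetry invariants
  larr <- random_levels_array(c(5, 5, 5), 4, seed = 99)
  P <- glcm(larr, c(1, 1, 0), 4)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
})

test_that("constant regions give Contrast 0 and MaximumProbability 1", {
  larr <- array(1L, c(3, 3, 3))
  d <- glcm_descriptors(glcm(larr, c(1, 0, 0), 4))
  expect_equal(d[["Contrast"]], 0)
  expect_equal(d[["MaximumProbability"]], 1)
  # correlation-type descriptors are undefined on a single gray level
  expect_true(is.nan(d[["Correlation"]]))
})

test_that("glrlm matches the hand example and the run-scanner oracle", {
  r <- array(NA_integer_, c(1, 5, 1))
  r[1, , 1] <- c(1L, 1L, 2L, 2L, 2L)
  R <- glrlm(r, c(0, 1, 0), 2)
  expect_equal(R[1, ], c(0, 1, 0))  # level 1: one run of length 2
  expect_equal(R[2, ], c(0, 0, 1))  # level 2: one run of length 3
  expect_equal(glrlm_descriptors(R, 5)[["ShortRunEmphasis"]],
               (1 / 4 + 1 / 9) / 2)
  # constant row is a single run
  cr <- array(1L, c(1, 7, 1))
  expect_equal(glrlm(cr, c(0, 1, 0), 1), matrix(c(rep(0, 6), 1), 1))
  offs <- offsets_13()
  for (s in 1:10) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    larr <- random_levels_array(dims, ng, p_mask = 0.75, seed = 200 + s)
    for (k in seq_len(nrow(offs)))
      expect_equal(glrlm(larr, offs[k, ], ng),
                   glrlm_oracle(larr, offs[k, ], ng),
                   label = sprintf("seed %d offset %d", s, k))
  }
})

test_that("texture block has 162 entries and consistent aggregation", {
  set.seed(5)
  msk <- array(TRUE, c(7, 7, 7))
  vals <- rnorm(sum(msk), 10, 2)
  tb <- texture_block(vals, msk)
  expect_length(tb, 162L)
  expect_true(all(is.finite(tb)))
  # aggregation identities: Mean lies within [Min, Max]; Range = Max - Min
  expect_true(tb[["glcm_Contrast_Min"]] <= tb[["glcm_Contrast_Mean"]])
  expect_true(tb[["glcm_Contrast_Mean"]] <= tb[["glcm_Contrast_Max"]])
  expect_equal(tb[["glcm_Contrast_Range"]],
               tb[["glcm_Contrast_Max"]] - tb[["glcm_Contrast_Min"]])
  # direct check of the Mean aggregation against per-direction values
  larr <- array(NA_integer_, dim(msk)); larr[msk] <- discretize(vals)
  per_dir <- vapply(seq_len(13), function(k)
    glcm_descriptors(glcm(larr, offsets_13()[k, ], 32))[["Contrast"]],
    numeric(1))
  expect_equal(tb[["glcm_Contrast_Mean"]], mean(per_dir))
  expect_equal(tb[["glcm_Contrast_Std"]], sd(per_dir))
})

test_that("haar sub-bands obey vanishing moments and perfect reconstruction", {
  const <- array(7, c(4, 4, 4))
  sb <- wavelet_subbands(const)
  expect_length(sb, 8L)
  for (nm in setdiff(names(sb), "LLL"))
    expect_equal(max(abs(sb[[nm]])), 0)
  expect_equal(sb$LLL, array(7 * sqrt(2)^3, c(4, 4, 4)))
  # haar pair identity: detail (a-b)/sqrt(2) along x, scaling sqrt(2) per
  # constant axis
  sbx <- wavelet_subbands(array(c(3, 5, 3, 5, 3, 5, 3, 5), c(2, 2, 2)))
  expect_equal(sbx$HLL[1, 1, 1], (3 - 5) / sqrt(2) * 2)
  expect_equal(sbx$LLL[1, 1, 1], (3 + 5) / sqrt(2) * 2)
  # perfect reconstruction on random volumes
  for (s in 1:5) {
    set.seed(s)
    v <- array(rnorm(prod(3:5)), 3:5)
    expect_lt(max(abs(wavelet_reconstruct(wavelet_subbands(v)) - v)), 1e-10)
  }
  expect_error(wavelet_subbands(array(1, c(1, 3, 3))), "support")
})

test_that("shape features behave on canonical solids", {
  # 10^3 cube: exact volume, near-cubic mesh area, sub-spherical sphericity
  arr <- array(FALSE, c(14, 14, 14)); arr[3:12, 3:12, 3:12] <- TRUE
  sf <- shape_features(vol_mask(arr, c(1, 1, 1)))
  expect_equal(sf[["shape_VoxelVolume"]], 1000)
  expect_lt(abs(sf[["shape_SurfaceArea"]] - 532.06), 0.5)  # frozen mesh value
  expect_lt(sf[["shape_Sphericity"]], 0.95)
  expect_equal(sf[["shape_Elongation"]], 1)
  expect_equal(sf[["shape_Flatness"]], 1)
  expect_equal(sf[["shape_Maximum3DDiameter"]], 9 * sqrt(3))
  # digital ball r = 15: sphericity approaches the spherical maximum
  sb <- shape_features(make_ball_mask(15, 37))
  expect_gt(sb[["shape_Sphericity"]], 0.9)
  expect_lt(sb[["shape_Sphericity"]], 1.02)
  expect_equal(sb[["shape_Elongation"]], 1, tolerance = 0.02)
  expect_equal(sb[["shape_Flatness"]], 1, tolerance = 0.02)
  # single voxel: face-area fallback
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  s1 <- shape_features(vol_mask(one, c(1, 1, 1)))
  expect_equal(s1[["shape_SurfaceArea"]], 6)
  expect_error(shape_features(vol_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("extract_all emits one finite value per registry entry, twice over", {
  set.seed(9)
  arr <- array(rnorm(16^3, 100, 10), c(16, 16, 16))
  g <- expand.grid(1:16, 1:16, 1:16)
  msk <- array((g[, 1] - 8.5)^2 + (g[, 2] - 8.5)^2 + (g[, 3] - 8.5)^2 <= 30,
               c(16, 16, 16))
  img <- vol_image(arr, c(1, 1, 1)); m <- vol_mask(msk, c(1, 1, 1))
  fv <- extract_all(img, m)
  expect_length(fv, 1618L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), default_registry()$name)
  expect_identical(fv, extract_all(img, m))
  # adding a constant leaves discretized texture features unchanged
  fv_shift <- extract_all(vol_image(arr + 250, c(1, 1, 1)), m)
  tex <- grep("^(glcm|glrlm)_", names(fv))
  expect_equal(fv[tex], fv_shift[tex])
  expect_equal(fv[["first_order_Mean"]] + 250, fv_shift[["first_order_Mean"]])
  # a constant region surfaces its degenerate descriptors by name
  expect_error(extract_all(vol_image(array(5, c(6, 6, 6)), c(1, 1, 1)),
                           vol_mask(array(TRUE, c(6, 6, 6)), c(1, 1, 1))),
               "non-finite feature")
})
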