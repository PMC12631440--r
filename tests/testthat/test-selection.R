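test_that("z-score normalization matches hand values and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 7))
  Z <- zscore_normalize(X)
  expect_equal(unname(Z[, "a"]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(colMeans(Z), c(a = 0, b = 0))
  expect_equal(apply(Z, 2, function(v) sqrt(mean((v - mean(v))^2))),
               c(a = 1, b = 1))
  expect_equal(zscore_normalize(Z), Z, ignore_attr = TRUE)  # idempotent
  # constant feature dropped with a warning
  expect_warning(Z2 <- zscore_normalize(cbind(a = c(1, 2, 3), k = c(4, 4, 4))),
                 "zero-variance")
  expect_identical(colnames(Z2), "a")
  expect_error(suppressWarnings(zscore_normalize(cbind(k = c(4, 4, 4)))),
               "zero variance")
  # train-only scope freezes moments on the training rows
  X3 <- cbind(f = c(0, 2, 4, 100))
  Z3 <- zscore_normalize(X3, "train_only", train_idx = 1:3)
  expect_equal(unname(Z3[1:3, 1]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
})

test_that("cohort splitting gives the 7:3 sizes deterministically", {
  s <- split_cohort(121, 0.7, seed = 5)
  expect_length(s$train, 84L)
  expect_length(s$test, 37L)
  expect_setequal(c(s$train, s$test), 1:121)
  expect_length(intersect(s$train, s$test), 0L)
  s10 <- split_cohort(10, 0.7, seed = 1)
  expect_length(s10$train, 7L)
  expect_length(s10$test, 3L)
  expect_identical(split_cohort(50, seed = 9), split_cohort(50, seed = 9))
  expect_false(identical(split_cohort(50, seed = 9), split_cohort(50, seed = 10)))
  expect_error(split_cohort(9), "at least 10")
})

test_that("median dichotomization applies the strict tie rule", {
  expect_identical(dichotomize_by_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_identical(dichotomize_by_median(c(3, 1, 4, 1, 5)), c(0L, 0L, 1L, 0L, 1L))
  expect_warning(lab <- dichotomize_by_median(rep(2, 5)), "all values equal")
  expect_identical(lab, rep(0L, 5))
})

test_that("stability selection recovers a planted feature and bounds counts", {
  cfg <- selection_config(seed = 11)
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    X <- matrix(rnorm(n * 40), n, 40,
                dimnames = list(NULL, sprintf("f%02d", 1:40)))
    y <- as.integer(X[, "f01"] + rnorm(n, sd = 0.4) > 0)
    Xn <- zscore_normalize(X)
    sel <- stability_select(Xn, y, cfg)
    expect_true(all(sel$counts >= 0 & sel$counts <= cfg$n_iterations))
    if ("f01" %in% sel$significant && sel$counts[["f01"]] == 25L)
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)  # planted feature found essentially always
  expect_error(stability_select(matrix(rnorm(40), 20), rep(1L, 20), cfg),
               "degenerate")
})

test_that("top-k ranking follows count, then coefficient, then name", {
  counts <- c(a = 25L, b = 24L, c = 20L, d = 19L, e = 25L, f = 21L, g = 22L)
  sel <- list(counts = counts,
              significant = names(counts)[counts >= 20L],
              coef_mean = setNames(rep(0, 7), names(counts)))
  cfg <- selection_config(top_k = 5)
  expect_identical(top_k_signature(sel, cfg), c("a", "e", "b", "g", "f"))
  # coefficient magnitude breaks the a/e tie
  sel2 <- sel; sel2$coef_mean[c("a", "e")] <- c(0.1, 0.9)
  expect_identical(top_k_signature(sel2, cfg)[1:2], c("e", "a"))
  # a significant set smaller than top_k shrinks the signature
  sel3 <- list(counts = c(x = 25L, y = 22L, z = 21L, w = 3L),
               significant = c("x", "y", "z"),
               coef_mean = c(x = 1, y = 1, z = 1, w = 1))
  expect_identical(top_k_signature(sel3, cfg), c("x", "y", "z"))
  # empty significant set falls back to top-k by count, with a message
  sel4 <- list(counts = c(p = 5L, q = 9L, r = 0L),
               significant = character(0),
               coef_mean = c(p = 1, q = 1, r = 0))
  expect_message(sig <- top_k_signature(sel4, cfg), "falling back")
  expect_identical(sig, c("q", "p"))
})

test_that("signature models fit, score and threshold sensibly", {
  set.seed(4)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  y <- as.integer(X[, "s1"] > 0)  # perfectly separable by s1
  m <- fit_signature_model(X, y, "s1", endpoint = "collagen",
                           region_mode = "combined")
  expect_s3_class(m, "tme_signature")
  expect_equal(roc_auc(predict(m, X), y), 1)
  expect_true(all(predict(m, X, type = "class") == y))
  # coefficients agree with an independent stats::lm fit (dual route)
  m <- fit_signature_model(X, y, c("s1", "s2"))
  lmfit <- lm(y ~ X[, "s1"] + X[, "s2"])
  expect_equal(unname(coef(m)), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(residuals(m)), unname(residuals(lmfit)), tolerance = 1e-10)
  # an orthogonal (null) signature scores at chance on fresh data
  y2 <- sample(0:1, n, replace = TRUE)
  m2 <- fit_signature_model(X, y2, "s3")
  Xnew <- matrix(rnorm(2000 * 3), 2000, 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  ynew <- sample(0:1, 2000, replace = TRUE)
  expect_lt(abs(roc_auc(predict(m2, Xnew), ynew) - 0.5), 0.05)
  # duplicated column triggers the ridge fallback rather than failure
  Xd <- cbind(X[, 1:2], dup = X[, 1])
  colnames(Xd) <- c("s1", "s2", "dup")
  expect_message(md <- fit_signature_model(Xd, y, colnames(Xd)), "ridge")
  expect_true(all(is.finite(coef(md))))
  expect_error(fit_signature_model(X, y, character(0)), "empty")
})

test_that("interpretability report gives correlations and shrinking CIs", {
  set.seed(6)
  make_rep <- function(n, B = 150) {
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
    y <- as.integer(0.8 * X[, 1] + rnorm(n) > 0)
    m <- fit_signature_model(X, y)
    interpretability_report(m, B = B, seed = 2)
  }
  r1 <- make_rep(100)
  expect_equal(diag(r1$correlation), c(u = 1, v = 1))
  expect_equal(r1$correlation, t(r1$correlation))
  expect_true(all(r1$standardized_coefficients$ci_low <=
                    r1$standardized_coefficients$estimate))
  expect_true(all(r1$standardized_coefficients$ci_high >=
                    r1$standardized_coefficients$estimate))
  # duplicated feature: pairwise correlation 1
  X <- matrix(rnorm(60), 30, 2); X[, 2] <- X[, 1]
  colnames(X) <- c("a", "b")
  y <- as.integer(X[, 1] + rnorm(30, sd = 2) > 0)
  m <- suppressMessages(fit_signature_model(X, y))
  expect_equal(interpretability_report(m, B = 20, seed = 1)$correlation["a", "b"], 1)
  # CI width shrinks roughly like 1/sqrt(n) between n = 100 and n = 400
  r4 <- make_rep(400)
  w1 <- mean(r1$standardized_coefficients$ci_high -
               r1$standardized_coefficients$ci_low)
  w4 <- mean(r4$standardized_coefficients$ci_high -
               r4$standardized_coefficients$ci_low)
  expect_lt(w4, w1 * 0.75)
})

test_that("selection configuration guards its invariants", {
  expect_error(selection_config(selection_threshold = 30), "exceed")
  expect_error(selection_config(top_k = 0), "at least 1")
  expect_error(selection_config(lambda_grid = c(0.2, 0.1)), "bracket")
  cfg <- selection_config()
  expect_true(min(cfg$lambda_grid) < 0.05 && max(cfg$lambda_grid) > 0.05)
})
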