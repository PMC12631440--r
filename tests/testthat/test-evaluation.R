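test_that("roc_auc matches pair counting, worked example and invariances", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5)), 0.5)
  set.seed(7)
  for (s in 1:60) {
    n <- sample(4:60, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * sc), lb), roc_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (s in 1:10) {
    sc <- rnorm(50); lb <- sample(0:1, 50, replace = TRUE)
    if (length(unique(lb)) < 2) next
    want <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_auc(sc, lb), want)
  }
})

test_that("confusion metrics reproduce the hand 2x2 table and extremes", {
  # TP=3 FP=1 FN=1 TN=5 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1, 0.2, 0.3, 0.15, 0.25)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm[["sensitivity"]], 0.75)
  expect_equal(cm[["specificity"]], 5 / 6)
  expect_equal(cm[["ppv"]], 0.75)
  expect_equal(cm[["npv"]], 5 / 6)
  expect_equal(cm[["accuracy"]], 0.8)
  low <- suppressWarnings(confusion_metrics(scores, labels, -1))
  expect_equal(low[["sensitivity"]], 1); expect_equal(low[["specificity"]], 0)
  hi <- suppressWarnings(confusion_metrics(scores, labels, 2))
  expect_equal(hi[["sensitivity"]], 0); expect_equal(hi[["specificity"]], 1)
  expect_warning(cmw <- confusion_metrics(scores, labels, 2), "PPV undefined")
  expect_true(is.nan(cmw[["ppv"]]))
})

test_that("bootstrap AUC intervals bracket the point estimate deterministically", {
  set.seed(3)
  sc <- c(rnorm(40, 1), rnorm(40))
  lb <- rep(1:0, each = 40)
  cfg <- eval_config(bootstrap_reps = 400, seed = 5)
  ci <- bootstrap_auc_ci(sc, lb, cfg)
  a <- roc_auc(sc, lb)
  expect_true(ci[["low"]] <= a && a <= ci[["high"]])
  expect_true(ci[["low"]] >= 0 && ci[["high"]] <= 1)
  expect_identical(ci, bootstrap_auc_ci(sc, lb, cfg))
  # perfect separation collapses the interval toward [1, 1]
  ci1 <- bootstrap_auc_ci(c(1, 2, 3, 11, 12, 13, 14), c(0, 0, 0, 1, 1, 1, 1),
                          eval_config(bootstrap_reps = 200, seed = 1))
  expect_equal(unname(ci1), c(1, 1))
})

test_that("delong test is conventional at zero difference and matches pROC", {
  set.seed(8)
  sc <- rnorm(60); lb <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  d <- delong_test(sc, sc, lb)
  expect_equal(d$p, 1)
  expect_equal(d$delta, 0)
  skip_if_not_installed("pROC")
  for (s in 1:8) {
    set.seed(100 + s)
    n <- 80
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    x <- rnorm(n) + lb
    y <- 0.5 * x + rnorm(n)
    ref <- pROC::roc.test(pROC::roc(lb, x, quiet = TRUE, direction = "<"),
                          pROC::roc(lb, y, quiet = TRUE, direction = "<"),
                          method = "delong")
    got <- delong_test(x, y, lb)
    expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("delong p agrees with a paired-permutation oracle on small data", {
  set.seed(19)
  n <- 40
  lb <- rep(0:1, each = 20)
  x <- rnorm(n) + 0.8 * lb
  y <- rnorm(n) + 0.4 * lb
  got <- delong_test(x, y, lb)$p
  # permutation null: randomly swap the two models per case
  B <- 1000
  d0 <- abs(roc_auc(x, lb) - roc_auc(y, lb))
  perm <- replicate(B, {
    sw <- runif(n) < 0.5
    xa <- ifelse(sw, y, x); yb <- ifelse(sw, x, y)
    abs(roc_auc(xa, lb) - roc_auc(yb, lb))
  })
  p_perm <- mean(perm >= d0 - 1e-12)
  expect_lt(abs(got - p_perm), 0.05)
})

test_that("bonferroni gate reproduces the printed thresholds", {
  expect_true(bonferroni_gate(0.009, 5))
  expect_false(bonferroni_gate(0.011, 5))
  expect_true(bonferroni_gate(0.012, 4))
  expect_identical(bonferroni_gate(c(0.02, 0.03), 2), c(TRUE, FALSE))
})

test_that("cross-validated AUC runs the pipeline per fold", {
  pf <- planted_feature_table(n = 150, p_noise = 20, d = 2, seed = 4)
  Xn <- zscore_normalize(pf$X)
  scfg <- selection_config(n_iterations = 8, selection_threshold = 6, seed = 2)
  cv <- cross_validated_auc(Xn, pf$y, scfg, eval_config(cv_folds = 5, seed = 3))
  expect_length(cv$fold_auc, 5L)
  expect_gt(cv$mean_auc, 0.75)  # strong planted signal found in-fold
  expect_true(cv$ci[["low"]] <= cv$mean_auc + 1e-9)
})

test_that("decision curves reproduce the closed forms", {
  dcc <- decision_curve_config()
  expect_error(decision_curve_config(c(0.2, 1)), "inside")
  set.seed(2)
  lb <- rep(0:1, each = 50)  # prevalence 0.5
  # treat-all closed form at pt = 0.2
  dc <- decision_curve(runif(100), lb, dcc)
  row <- dc[abs(dc$pt - 0.2) < 1e-9, ]
  expect_equal(row$nb_all, 0.5 - 0.5 * 0.25)
  expect_equal(row$nb_all, 0.375)
  expect_true(all(dc$nb_none == 0))
  # perfect classifier: NB = prevalence at every threshold
  perf <- decision_curve(lb, lb, dcc)
  expect_true(all(abs(perf$nb_model - 0.5) < 1e-12))
  # model net benefit never exceeds prevalence
  expect_true(all(dc$nb_model <= 0.5 + 1e-12))
  # linear scores are min-max calibrated before thresholding
  dc2 <- decision_curve(rnorm(100, 0, 3), lb, dcc)
  expect_true(all(is.finite(dc2$nb_model)))
})

test_that("subtype comparison excludes tiny strata and tests pairs", {
  set.seed(14)
  n <- 150
  subtype <- factor(c(rep("A", 70), rep("B", 76), rep("tiny", 4)))
  lb <- sample(0:1, n, replace = TRUE)
  sc <- rnorm(n) + 0.8 * lb
  res <- subtype_stratified_compare(sc, lb, subtype,
                                    eval_config(bootstrap_reps = 200, seed = 2))
  expect_named(res$auc, c("A", "B"))
  expect_match(res$excluded[["tiny"]], "n = 4")
  expect_equal(nrow(res$comparisons), 1L)
  expect_true(res$comparisons$p >= 0 && res$comparisons$p <= 1)
  expect_equal(res$auc[["A"]], roc_auc(sc[subtype == "A"], lb[subtype == "A"]))
})

test_that("subtype bootstrap p-values are roughly calibrated under the null", {
  set.seed(33)
  rej <- 0L
  n_sim <- 120
  for (s in 1:n_sim) {
    lb <- sample(0:1, 120, replace = TRUE, prob = c(0.5, 0.5))
    sc <- rnorm(120) + 0.7 * lb      # same quality in both strata
    subtype <- factor(rep(c("A", "B"), 60))
    res <- subtype_stratified_compare(sc, lb, subtype,
                                      eval_config(bootstrap_reps = 150,
                                                  seed = s))
    if (!is.null(res$comparisons) && res$comparisons$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_sim, 0.005)
  expect_lt(rej / n_sim, 0.13)
})

test_that("cohort balance report flags effects with Cohen's d labels", {
  set.seed(5)
  df <- data.frame(age = rnorm(60, 50, 10),
                   grp = factor(sample(c("x", "y"), 60, replace = TRUE)))
  same <- cohort_balance_report(df, df)
  expect_equal(same$effect[same$variable == "age"], 0)
  expect_equal(same$effect[same$variable == "grp"], 0)
  # means 10 vs 12 with common SD 2 -> |d| = 1 (large)
  a <- data.frame(v = rnorm(4000, 10, 2))
  b <- data.frame(v = rnorm(4000, 12, 2))
  rep2 <- cohort_balance_report(a, b)
  expect_equal(abs(rep2$effect), 1, tolerance = 0.08)
  expect_identical(rep2$effect_label, "large")
  # threshold labels
  lab <- function(d) as.character(cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
                                      labels = c("negligible", "small",
                                                 "medium", "large")))
  expect_identical(lab(0.3), "small")
  expect_identical(lab(0.6), "medium")
  expect_identical(lab(0.9), "large")
})
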