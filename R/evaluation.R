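#' Evaluation configuration
#'
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param ci_percentiles CI percentiles (default 2.5 and 97.5).
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return An `eval_config` list.
#' @export
eval_config <- function(bootstrap_reps = 1000L, ci_percentiles = c(2.5, 97.5),
                        cv_folds = 5L, seed = 1L) {
  if (length(ci_percentiles) != 2L || any(ci_percentiles <= 0) ||
      any(ci_percentiles >= 100) || diff(ci_percentiles) <= 0)
    stopf("ci_percentiles must be ordered and inside (0, 100)")
  structure(list(bootstrap_reps = as.integer(bootstrap_reps),
                 ci_percentiles = ci_percentiles,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "eval_config")
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic: the fraction of (positive, negative) score pairs
#' that are concordant, counting ties as one half.
#'
#' @param scores Continuous scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix metrics at a threshold
#'
#' Predicts positive when `score >= threshold` and reports accuracy,
#' sensitivity, specificity, PPV and NPV. An empty predicted-positive (or
#' -negative) set makes PPV (NPV) `NaN` with a warning rather than silently 0.
#'
#' @param scores Continuous scores.
#' @param labels 0/1 labels, both classes present.
#' @param threshold Decision threshold.
#' @return Named numeric vector of the five rates.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  if (tp + fp == 0L) warnf("no predicted positives; PPV undefined")
  if (tn + fn == 0L) warnf("no predicted negatives; NPV undefined")
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
    npv = if (tn + fn > 0) tn / (tn + fn) else NaN)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Case-resampling bootstrap; replicates that draw a single class are
#' redrawn. The interval is the 2.5/97.5 percentile pair of the replicate
#' AUCs (configurable).
#'
#' @param scores,labels As in [roc_auc()].
#' @param config An [eval_config()].
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, config = eval_config()) {
  labels <- as.integer(labels)
  n <- length(scores)
  aucs <- with_seed(config$seed, {
    vapply(seq_len(config$bootstrap_reps), function(b) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  q <- quantile(aucs, config$ci_percentiles / 100, names = FALSE)
  c(low = q[1], high = q[2])
}

# DeLong structural components: V10 (per positive) and V01 (per negative),
# computed with midranks.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two models scored on the same
#' cases, using the structural-components estimator of the variance of the
#' paired AUC difference. Identical score vectors return a difference of 0
#' and p = 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels 0/1 labels, both classes present.
#' @return List with `auc_a`, `auc_b`, `delta`, `variance`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stopf("scores and labels must be paired")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  delta <- ca$auc - cb$auc
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = 0,
                variance = 0, z = 0, p = 1))
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= 0) {
    if (abs(delta) > 1e-12)
      stopf("degenerate configuration: zero variance with nonzero AUC difference")
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                variance = 0, z = 0, p = 1))
  }
  z <- delta / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, variance = v,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Bonferroni significance gate
#'
#' Flags p-values significant when `p < alpha / m`; with `m` = 5, 4 or 2 this
#' reproduces the thresholds 0.01, 0.0125 and 0.025 used in the comparison
#' grids.
#'
#' @param p_values Numeric vector.
#' @param n_comparisons Number of comparisons `m`.
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector.
#' @export
bonferroni_gate <- function(p_values, n_comparisons, alpha = 0.05) {
  stopifnot(n_comparisons >= 1)
  p_values < alpha / n_comparisons
}

#' Cross-validated AUC of the full selection + fit pipeline
#'
#' Stratified k-fold cross-validation in which the entire signature pipeline
#' (stability selection, top-k signature, linear fit) is re-run inside each
#' training fold and scored on the held-out fold.
#'
#' @param X Normalized feature matrix.
#' @param y Binary 0/1 labels.
#' @param sel_cfg A [selection_config()].
#' @param config An [eval_config()].
#' @param pipeline Optional custom function `(X_train, y_train) -> model`
#'   whose result is scored with [predict()].
#' @return List with `fold_auc` (length `cv_folds`), `mean_auc`, and `ci`
#'   (percentile interval across folds).
#' @export
cross_validated_auc <- function(X, y, sel_cfg = selection_config(),
                                config = eval_config(), pipeline = NULL) {
  X <- as.matrix(X); y <- as.integer(y)
  k <- config$cv_folds
  folds <- with_seed(config$seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  if (is.null(pipeline))
    pipeline <- function(Xtr, ytr) {
      sel <- stability_select(Xtr, ytr, sel_cfg)
      sig <- top_k_signature(sel, sel_cfg)
      if (length(sig) == 0L) sig <- colnames(Xtr)[which.max(sel$counts)]
      fit_signature_model(Xtr, ytr, sig, selection = sel)
    }
  fold_auc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- pipeline(X[tr, , drop = FALSE], y[tr])
    roc_auc(predict(model, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  ci <- quantile(fold_auc, config$ci_percentiles / 100, names = FALSE)
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
       ci = c(low = ci[1], high = ci[2]))
}

#' Decision-curve configuration
#'
#' @param thresholds Threshold probabilities, strictly inside (0, 1);
#'   default `seq(0.10, 0.40, 0.01)`.
#' @return A `decision_curve_config` list.
#' @export
decision_curve_config <- function(thresholds = seq(0.10, 0.40, by = 0.01)) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stopf("thresholds must be strictly inside (0, 1)")
  structure(list(thresholds = thresholds), class = "decision_curve_config")
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit of treating at probability threshold `pt`:
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)`, compared with treat-all
#' (`prev - (1 - prev) * pt / (1 - pt)`) and treat-none (0). Scores outside
#' \[0, 1\] are min-max calibrated to probabilities first (optionally against
#' a reference score range, e.g. the training scores).
#'
#' @param scores Continuous scores or probabilities.
#' @param labels 0/1 labels.
#' @param config A [decision_curve_config()].
#' @param calibration_range Optional length-2 range used for min-max
#'   calibration (default: range of `scores`).
#' @return Data.frame with columns `pt`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(scores, labels, config = decision_curve_config(),
                           calibration_range = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  prob <- scores
  if (min(scores) < 0 || max(scores) > 1) {
    r <- if (is.null(calibration_range)) range(scores) else calibration_range
    prob <- (scores - r[1]) / max(r[2] - r[1], .Machine$double.eps)
    prob <- pmin(pmax(prob, 0), 1)
  }
  prev <- mean(labels)
  out <- lapply(config$thresholds, function(pt) {
    w <- pt / (1 - pt)
    pred <- prob >= pt
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    data.frame(pt = pt,
               nb_model = tp / n - fp / n * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  })
  do.call(rbind, out)
}

#' Subtype-stratified AUC comparison
#'
#' Per-subtype AUCs with pairwise bootstrap tests of the AUC difference
#' between subtypes. Subtypes with fewer than `min_n` cases or a single label
#' class are excluded (with the reason recorded), mirroring the exclusion of
#' the 4-case HER2-enriched stratum in the source analysis. The p-value
#' inverts the stratified case-resampling bootstrap distribution of the AUC
#' difference (two-sided); Bonferroni gating uses the number of performed
#' comparisons.
#'
#' @param scores Continuous scores.
#' @param labels 0/1 labels.
#' @param subtype Factor of subtype membership.
#' @param config An [eval_config()].
#' @param min_n Minimum stratum size (default 10).
#' @return List with `auc` (per evaluated subtype), `excluded` (named reasons),
#'   and `comparisons` (data.frame with delta, p, and Bonferroni flag).
#' @export
subtype_stratified_compare <- function(scores, labels, subtype,
                                       config = eval_config(), min_n = 10L) {
  labels <- as.integer(labels)
  subtype <- droplevels(factor(subtype))
  keep <- character(0); excluded <- character(0)
  for (s in levels(subtype)) {
    idx <- subtype == s
    if (sum(idx) < min_n)
      excluded[s] <- sprintf("n = %d < %d", sum(idx), min_n)
    else if (length(unique(labels[idx])) < 2L)
      excluded[s] <- "single label class"
    else keep <- c(keep, s)
  }
  aucs <- vapply(keep, function(s)
    roc_auc(scores[subtype == s], labels[subtype == s]), numeric(1))
  comps <- NULL
  if (length(keep) >= 2L) {
    pairs <- utils::combn(keep, 2)
    B <- config$bootstrap_reps
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      s1 <- pairs[1, k]; s2 <- pairs[2, k]
      i1 <- which(subtype == s1); i2 <- which(subtype == s2)
      delta <- aucs[[s1]] - aucs[[s2]]
      deltas <- with_seed(derive_seed(config$seed, paste0("subtype", k)), {
        vapply(seq_len(B), function(b) {
          repeat {
            b1 <- sample(i1, replace = TRUE)
            if (length(unique(labels[b1])) == 2L) break
          }
          repeat {
            b2 <- sample(i2, replace = TRUE)
            if (length(unique(labels[b2])) == 2L) break
          }
          roc_auc(scores[b1], labels[b1]) - roc_auc(scores[b2], labels[b2])
        }, numeric(1))
      })
      p <- 2 * min(mean(deltas <= 0) + 0.5 * mean(deltas == 0),
                   mean(deltas >= 0) + 0.5 * mean(deltas == 0))
      p <- min(1, max(p, 2 / B))
      data.frame(subtype_a = s1, subtype_b = s2, delta = delta, p = p)
    })
    comps <- do.call(rbind, rows)
    comps$significant <- bonferroni_gate(comps$p, nrow(comps))
  }
  list(auc = aucs, excluded = excluded, comparisons = comps)
}

#' Train/test cohort-balance report
#'
#' Per-variable balance statistics between two cohorts: for continuous
#' variables a Shapiro-Wilk normality check chooses Welch's t test or the
#' Mann-Whitney U test, and Cohen's d (pooled-SD form) is reported with the
#' conventional small/medium/large labels at 0.2/0.5/0.8; for categorical
#' variables a chi-square (or Fisher, on sparse tables) test and the maximum
#' absolute difference in category proportions.
#'
#' @param train,test Data.frames with a shared column schema.
#' @return Data.frame with one row per variable: test used, p-value, effect
#'   size and its label.
#' @export
cohort_balance_report <- function(train, test) {
  vars <- intersect(names(train), names(test))
  rows <- lapply(vars, function(v) {
    a <- train[[v]]; b <- test[[v]]
    if (is.numeric(a)) {
      normal <- length(unique(a)) > 3 && length(unique(b)) > 3 &&
        shapiro.test(a)$p.value > 0.05 && shapiro.test(b)$p.value > 0.05
      p <- if (normal) t.test(a, b)$p.value
      else suppressWarnings(wilcox.test(a, b)$p.value)
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
      d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
      lab <- cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
                 labels = c("negligible", "small", "medium", "large"))
      data.frame(variable = v, type = "continuous",
                 test = if (normal) "welch_t" else "mann_whitney",
                 p = p, effect = d, effect_label = as.character(lab))
    } else {
      a <- factor(a); b <- factor(b, levels = levels(a))
      tab <- rbind(table(a), table(b))
      p <- tryCatch({
        if (any(suppressWarnings(chisq.test(tab))$expected < 5))
          fisher.test(tab)$p.value
        else chisq.test(tab)$p.value
      }, error = function(e) NA_real_)
      pd <- max(abs(prop.table(tab, 1)[1, ] - prop.table(tab, 1)[2, ]))
      data.frame(variable = v, type = "categorical",
                 test = "chisq_or_fisher", p = p, effect = pd,
                 effect_label = "proportion_difference")
    }
  })
  do.call(rbind, rows)
}
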