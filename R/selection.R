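#' Selection configuration
#'
#' Settings of the signature-discovery stage: 7:3 train/test split, z-score
#' normalization, and iterated-LASSO stability selection (25 iterations of
#' fivefold cross-validated LASSO; features selected in at least 20
#' iterations are significant; the top 5 form the signature). The lambda grid
#' is log-spaced and brackets 0.05, the cross-validated optimum reported for
#' the original cohort; `fixed_lambda` reproduces that fixed-penalty variant.
#'
#' @param split_ratio Training fraction (default 0.7).
#' @param n_folds CV folds inside each LASSO iteration (default 5).
#' @param n_iterations LASSO iterations (default 25).
#' @param selection_threshold Minimum selection count for significance
#'   (default 20).
#' @param top_k Signature size cap (default 5).
#' @param lambda_grid Decreasing positive penalty grid; must bracket 0.05.
#' @param lambda_rule `"1se"` (default): the largest penalty within one
#'   standard error of the CV optimum — the conservative choice that keeps
#'   stability selection sparse and its significant set empty on
#'   signal-free data; `"min"`: the CV-error minimizer.
#' @param fixed_lambda Optional fixed penalty replacing per-iteration CV.
#' @param seed Integer seed.
#' @param normalization_scope `"all_cases"` (as in the original analysis:
#'   normalize before splitting) or `"train_only"`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(split_ratio = 0.7,
                             n_folds = 5L,
                             n_iterations = 25L,
                             selection_threshold = 20L,
                             top_k = 5L,
                             lambda_grid = exp(seq(log(1), log(0.005),
                                                   length.out = 60)),
                             lambda_rule = c("1se", "min"),
                             fixed_lambda = NULL,
                             seed = 1L,
                             normalization_scope = c("all_cases", "train_only")) {
  normalization_scope <- match.arg(normalization_scope)
  lambda_rule <- match.arg(lambda_rule)
  if (selection_threshold > n_iterations)
    stopf("selection_threshold must not exceed n_iterations")
  if (top_k < 1L) stopf("top_k must be at least 1")
  if (any(lambda_grid <= 0)) stopf("lambda grid must be positive")
  if (min(lambda_grid) > 0.05 || max(lambda_grid) < 0.05)
    stopf("lambda grid must bracket 0.05")
  structure(list(split_ratio = split_ratio, n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 selection_threshold = as.integer(selection_threshold),
                 top_k = as.integer(top_k),
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 lambda_rule = lambda_rule,
                 fixed_lambda = fixed_lambda,
                 seed = as.integer(seed),
                 normalization_scope = normalization_scope),
            class = "selection_config")
}

#' Z-score normalize a feature table
#'
#' Centers and scales each feature to mean 0, SD 1 (population SD) over the
#' chosen scope. Zero-variance features are dropped with a warning. When
#' `scope = "train_only"`, means/SDs come from the training rows but are
#' applied to all rows.
#'
#' @param X Numeric matrix (cases x features).
#' @param scope `"all_cases"` or `"train_only"`.
#' @param train_idx Row indices of the training cohort (required for
#'   `train_only`).
#' @return Normalized matrix with attributes `center` and `scale`.
#' @export
zscore_normalize <- function(X, scope = c("all_cases", "train_only"),
                             train_idx = NULL) {
  scope <- match.arg(scope)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 cases")
  ref <- if (scope == "train_only") {
    if (is.null(train_idx)) stopf("train_idx required for train_only scope")
    X[train_idx, , drop = FALSE]
  } else X
  ctr <- colMeans(ref)
  n <- nrow(ref)
  scl <- sqrt(colMeans(sweep(ref, 2, ctr)^2))
  keep <- scl > 0
  if (!any(keep)) stopf("all features have zero variance")
  if (any(!keep))
    warnf("dropping %d zero-variance feature(s): %s", sum(!keep),
          paste(head(colnames(X)[!keep], 5), collapse = ", "))
  out <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  attr(out, "center") <- ctr[keep]
  attr(out, "scale") <- scl[keep]
  out
}

#' Random 7:3 cohort split
#'
#' @param n Number of cases (>= 10).
#' @param ratio Training fraction.
#' @param seed Integer seed.
#' @return List with integer vectors `train` (`floor(ratio * n)` cases) and
#'   `test`.
#' @export
split_cohort <- function(n, ratio = 0.7, seed = 1L) {
  if (n < 10L) stopf("n must be at least 10")
  n_train <- floor(ratio * n)
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Median dichotomization
#'
#' Label 1 for values strictly above the median; values equal to the median
#' get label 0 (tie rule).
#'
#' @param values Numeric vector (length >= 2).
#' @return Integer 0/1 vector.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  lab <- as.integer(values > median(values))
  if (all(lab == 0L) && length(unique(values)) == 1L)
    warnf("all values equal; labels all 0")
  lab
}

#' Iterated-LASSO stability selection
#'
#' Runs `n_iterations` LASSO fits of the (gaussian) binary label on the
#' normalized training features. Each iteration re-randomizes the fivefold CV
#' partition, picks the penalty with minimal CV error from the grid (or uses
#' `fixed_lambda`), and records which features receive nonzero coefficients.
#' Features selected at least `selection_threshold` times form the
#' significant set.
#'
#' @param X Normalized training feature matrix.
#' @param y Binary 0/1 training labels.
#' @param config A [selection_config()].
#' @return List with `counts` (named selection counts), `significant`
#'   (feature names), and `coef_mean` (mean absolute coefficient over
#'   iterations).
#' @export
stability_select <- function(X, y, config = selection_config()) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stopf("labels are degenerate (one class)")
  if (anyNA(X)) stopf("missing values in features")
  if (nrow(X) <= config$n_folds) stopf("training cohort smaller than fold count")
  p <- ncol(X)
  counts <- setNames(integer(p), colnames(X))
  coef_abs <- setNames(numeric(p), colnames(X))
  with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      if (is.null(config$fixed_lambda)) {
        foldid <- sample(rep_len(seq_len(config$n_folds), nrow(X)))
        cvf <- glmnet::cv.glmnet(X, y, family = "gaussian",
                                 lambda = config$lambda_grid,
                                 foldid = foldid, standardize = FALSE)
        lam <- if (config$lambda_rule == "1se") cvf$lambda.1se else cvf$lambda.min
        cf <- as.numeric(coef(cvf, s = lam))[-1]
      } else {
        fit <- glmnet::glmnet(X, y, family = "gaussian",
                              lambda = config$lambda_grid, standardize = FALSE)
        cf <- as.numeric(coef(fit, s = config$fixed_lambda, exact = FALSE))[-1]
      }
      nz <- cf != 0
      counts[nz] <- counts[nz] + 1L
      coef_abs <- coef_abs + abs(cf)
    }
  })
  list(counts = counts,
       significant = names(counts)[counts >= config$selection_threshold],
       coef_mean = coef_abs / config$n_iterations)
}

#' Top-k signature from selection counts
#'
#' Ranks candidates by selection count, breaking ties by mean absolute
#' coefficient, then lexicographically. Returns up to `top_k` names from the
#' significant set; if the set is empty, falls back to the top `top_k` by
#' count (with a message).
#'
#' @param selection Result of [stability_select()].
#' @param config A [selection_config()].
#' @return Character vector of feature names (possibly empty).
#' @export
top_k_signature <- function(selection, config = selection_config()) {
  counts <- selection$counts
  if (length(counts) == 0L) stopf("empty selection counts")
  ord <- order(-counts, -selection$coef_mean, names(counts))
  ranked <- names(counts)[ord]
  pool <- selection$significant
  if (length(pool) == 0L) {
    message("significant set empty; falling back to top-", config$top_k,
            " by selection count")
    pool <- ranked[counts[ord] > 0]
    if (length(pool) == 0L) return(character(0))
  }
  ranked_pool <- ranked[ranked %in% pool]
  head(ranked_pool, config$top_k)
}
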