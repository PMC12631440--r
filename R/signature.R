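#' Fit a linear radiomic signature model
#'
#' Ordinary least-squares regression of the binary label on the selected
#' signature features (linear probability scoring, as in the source analysis;
#' set `family = "logistic"` for a logistic alternative). The operating
#' threshold for classification is the Youden-optimal point on the training
#' ROC. A singular design falls back to a small ridge penalty (with a
#' message).
#'
#' @param X Training feature matrix (normalized), containing the signature
#'   columns.
#' @param y Binary 0/1 training labels.
#' @param signature Character vector of selected feature names.
#' @param endpoint,region_mode Optional provenance tags.
#' @param selection Optional [stability_select()] result to store.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return A `tme_signature` model object.
#' @export
fit_signature_model <- function(X, y, signature = colnames(X),
                                endpoint = NA_character_,
                                region_mode = NA_character_,
                                selection = NULL,
                                family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(signature) == 0L) stopf("signature is empty")
  X <- as.matrix(X)[, signature, drop = FALSE]
  if (length(unique(y)) < 2L) stopf("labels are degenerate (one class)")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (family == "linear") {
    qrx <- qr(Xd)
    if (qrx$rank < ncol(Xd)) {
      message("singular design; using ridge fallback (lambda = 1e-8)")
      cf <- solve(crossprod(Xd) + diag(1e-8, ncol(Xd)), crossprod(Xd, y))[, 1]
    } else {
      cf <- qr.coef(qrx, y)
    }
  } else {
    fit <- stats::glm.fit(Xd, y, family = stats::binomial())
    cf <- fit$coefficients
  }
  scores <- drop(Xd %*% cf)
  obj <- structure(list(coefficients = cf[-1], intercept = cf[[1]],
                        signature = signature, family = family,
                        endpoint = endpoint, region_mode = region_mode,
                        threshold = NA_real_,
                        selection_counts = selection$counts,
                        y_train = y, scores_train = scores,
                        X_train = X),
                   class = "tme_signature")
  obj$threshold <- youden_threshold(scores, y)
  obj
}

#' Youden-optimal operating threshold
#'
#' Score cut maximizing sensitivity + specificity - 1 on the given data;
#' among equal-J cuts the midpoint of the optimal score gap is returned.
#'
#' @param scores Continuous scores.
#' @param labels 0/1 labels.
#' @return Threshold on the score scale (predict positive when
#'   `score >= threshold`).
#' @export
youden_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  j <- vapply(cuts, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}

#' @export
predict.tme_signature <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$signature, drop = FALSE]
  sc <- drop(X %*% object$coefficients) + object$intercept
  if (object$family == "logistic") sc <- 1 / (1 + exp(-sc))
  if (type == "class") as.integer(sc >= object$threshold) else sc
}

#' @export
coef.tme_signature <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
residuals.tme_signature <- function(object, ...) {
  object$y_train - object$scores_train
}

#' @export
print.tme_signature <- function(x, ...) {
  cat(sprintf("<tme_signature> endpoint %s, region mode %s (%s model)\n",
              x$endpoint, x$region_mode, x$family))
  cat("signature:", paste(x$signature, collapse = ", "), "\n")
  cat(sprintf("threshold (Youden, training): %.4f\n", x$threshold))
  invisible(x)
}

#' @export
summary.tme_signature <- function(object, ...) {
  auc <- roc_auc(object$scores_train, object$y_train)
  cm <- confusion_metrics(object$scores_train, object$y_train, object$threshold)
  out <- list(model = object, train_auc = auc, train_confusion = cm)
  class(out) <- "summary.tme_signature"
  out
}

#' @export
print.summary.tme_signature <- function(x, ...) {
  print(x$model)
  cat(sprintf("training AUC: %.3f\n", x$train_auc))
  print(round(x$train_confusion, 3))
  invisible(x)
}

#' @export
plot.tme_signature <- function(x, B = 200L, seed = 1L, ...) {
  rep <- interpretability_report(x, B = B, seed = seed)
  sc <- rep$standardized_coefficients
  mid <- barplot(sc$estimate, names.arg = rownames(sc), las = 2,
                 ylab = "standardized coefficient",
                 ylim = range(c(0, sc$ci_low, sc$ci_high)) * 1.1, ...)
  arrows(mid, sc$ci_low, mid, sc$ci_high, angle = 90, code = 3, length = 0.04)
  invisible(rep)
}

#' Interpretability report for a signature model
#'
#' Standardized coefficients with percentile-bootstrap 95% confidence
#' intervals (case resampling, model refit per replicate) and the Pearson
#' correlation matrix of the signature features.
#'
#' @param model A `tme_signature` fitted with stored training data.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `standardized_coefficients` (data.frame with columns
#'   estimate/ci_low/ci_high) and `correlation` (matrix).
#' @export
interpretability_report <- function(model, B = 1000L, seed = 1L) {
  stopifnot(inherits(model, "tme_signature"))
  X <- model$X_train
  y <- model$y_train
  sdx <- apply(X, 2, sd)
  sdy <- sd(y)
  std <- model$coefficients * sdx / sdy
  boot <- with_seed(seed, {
    t(replicate(B, {
      idx <- sample.int(nrow(X), replace = TRUE)
      while (length(unique(y[idx])) < 2L)
        idx <- sample.int(nrow(X), replace = TRUE)
      m <- fit_signature_model(X[idx, , drop = FALSE], y[idx],
                               signature = model$signature,
                               family = model$family)
      m$coefficients * apply(X[idx, , drop = FALSE], 2, sd) / sd(y[idx])
    }))
  })
  ci <- apply(boot, 2, quantile, c(0.025, 0.975))
  list(standardized_coefficients = data.frame(
    estimate = std, ci_low = ci[1, ], ci_high = ci[2, ],
    row.names = model$signature),
    correlation = cor(X))
}
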