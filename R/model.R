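# Outcome modelling: empirical ROC machinery and multivariate binary
# logistic regression with imbalance-adjusted (stratified) bootstrap
# performance estimation.

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the unique score values from high to low; tied scores
#' are grouped, so all-equal scores give the chance diagonal (AUC 0.5).
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return list: `thresholds`, `sensitivity`, `specificity` (per threshold,
#'   prediction positive iff score >= threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_gdr("gdr_value_error", "scores and labels must align without NA")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_gdr("gdr_value_error", "ROC needs both outcome classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), 0)
  tpr <- tp / n1
  fpr <- fp / n0
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
  list(thresholds = thr, sensitivity = tpr, specificity = 1 - fpr, auc = auc)
}

.youden_point <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  i <- which.max(j)
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i])
}

#' Logistic outcome model with stratified bootstrap performance estimation
#'
#' Coefficients come from the full-data binomial GLM (Wald 95% CIs).
#' Prediction performance is estimated by B stratified bootstrap resamples:
#' each resample draws within class with replacement preserving the class
#' proportions (the imbalance adjustment), the model is refit on the
#' resample and scored on the out-of-bag cases; AUC, sensitivity and
#' specificity at the Youden-optimal out-of-bag operating point are averaged
#' over replicates. Replicates whose out-of-bag set lacks a class are
#' dropped (reported as `B_effective`).
#'
#' @param x data.frame (or matrix) of predictor deltas, no missing values.
#' @param y 0/1 outcome vector, >= 3 cases per class.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling stream.
#' @return object of class `model_result`: `coefficients` (estimate, ci_lo,
#'   ci_hi), `auc`, `sensitivity`, `specificity`, `auc_sd`,
#'   `auc_quantiles`, `B`, `B_effective`, `separable`, `features`.
#' @export
fit_logistic_bootstrap <- function(x, y, B = 1000L, seed = 1L) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (anyNA(x) || anyNA(y))
    stop_gdr("gdr_value_error", "missing values among predictors or labels")
  if (sum(y == 1L) < 3L || sum(y == 0L) < 3L)
    stop_gdr("gdr_value_error", "need >= 3 cases per class")
  dat <- cbind(x, .y = y)
  separable <- FALSE
  full <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- stats::coef(full)
  se <- sqrt(diag(summary(full)$cov.scaled))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se))

  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  set.seed(derive_seed(seed, "bootstrap"))
  aucs <- sens <- spec <- numeric(0)
  for (b in seq_len(B)) {
    inbag <- c(sample(idx1, length(idx1), replace = TRUE),
               sample(idx0, length(idx0), replace = TRUE))
    oob <- setdiff(seq_along(y), unique(inbag))
    if (length(unique(y[oob])) < 2L) next
    fit <- suppressWarnings(
      stats::glm(.y ~ ., family = stats::binomial(), data = dat[inbag, ]))
    pr <- suppressWarnings(
      stats::predict(fit, newdata = dat[oob, , drop = FALSE], type = "response"))
    roc <- roc_curve(pr, y[oob])
    op <- .youden_point(roc)
    aucs <- c(aucs, roc$auc); sens <- c(sens, op$sensitivity)
    spec <- c(spec, op$specificity)
  }
  if (!length(aucs))
    stop_gdr("gdr_value_error", "no bootstrap replicate had both classes out of bag")
  structure(list(features = names(x), coefficients = coefs,
                 auc = mean(aucs), sensitivity = mean(sens),
                 specificity = mean(spec), auc_sd = stats::sd(aucs),
                 auc_quantiles = stats::quantile(aucs, c(0.025, 0.5, 0.975)),
                 B = B, B_effective = length(aucs), separable = separable),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s | AUC %.3f, sens %.3f, spec %.3f (B_eff=%d/%d)%s>\n",
              paste(x$features, collapse = "+"), x$auc, x$sensitivity,
              x$specificity, x$B_effective, x$B,
              if (x$separable) " [separable]" else ""))
  invisible(x)
}
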