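#' Classification metrics, ROC/AUC, cross-validation, applicability domain
#'
#' @name validation
NULL

#' Confusion counts
#'
#' @param TP,FN,TN,FP non-negative integer cells (actives are the
#'   positive class).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  vals <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(vals < 0) || any(vals != round(vals))) {
    mtq_stop("mtqsar_metric_error", "confusion cells must be non-negative integers")
  }
  structure(as.list(vals), class = "confusion_counts")
}

#' Confusion counts from observed and predicted labels
#'
#' @param observed,predicted +1/-1 vectors.
#' @return A `confusion_counts` object.
#' @export
count_confusion <- function(observed, predicted) {
  confusion_counts(TP = sum(observed == 1 & predicted == 1),
                   FN = sum(observed == 1 & predicted == -1),
                   TN = sum(observed == -1 & predicted == -1),
                   FP = sum(observed == -1 & predicted == 1))
}

#' Classification report from confusion counts
#'
#' Sensitivity = 100 TP/(TP+FN); specificity = 100 TN/(TN+FP); accuracy =
#' 100 (TP+TN)/n; F-measure = active-class F1; MCC by the standard
#' four-term formula, defined as 0 when any marginal is zero.
#'
#' @param counts a `confusion_counts`.
#' @param auc optional AUC to carry in the report.
#' @return A `classification_report` list with `sensitivity`,
#'   `specificity`, `accuracy` (percent), `f_measure`, `mcc`, `auc` and
#'   the counts.
#' @export
classification_report <- function(counts, auc = NULL) {
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  pos <- TP + FN; neg <- TN + FP
  if (pos == 0 || neg == 0) {
    mtq_stop("mtqsar_metric_error", "both classes must be represented")
  }
  sens <- 100 * TP / pos
  spec <- 100 * TN / neg
  acc <- 100 * (TP + TN) / (pos + neg)
  f1 <- if (TP == 0) 0 else {
    prec <- TP / (TP + FP); rec <- TP / pos
    2 * prec * rec / (prec + rec)
  }
  TPd <- as.numeric(TP); FNd <- as.numeric(FN)
  TNd <- as.numeric(TN); FPd <- as.numeric(FP)
  denom <- (TPd + FPd) * (TPd + FNd) * (TNd + FPd) * (TNd + FNd)
  mcc <- if (denom == 0) 0 else {
    (TPd * TNd - FPd * FNd) / sqrt(denom)
  }
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 f_measure = f1, mcc = mcc, auc = auc, counts = counts),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  F %.3f  MCC %.3f%s\n",
    x$sensitivity, x$specificity, x$accuracy, x$f_measure, x$mcc,
    if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' Ties contribute one half; constant scores give 0.5.
#'
#' @param scores numeric scores (higher = more active).
#' @param labels +1/-1 labels (both classes required).
#' @return Area under the ROC curve in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    mtq_stop("mtqsar_metric_error", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation with pooled predictions
#'
#' Folds are stratified by class; out-of-fold predictions are pooled over
#' all folds and a single [classification_report()] computed from them
#' (with an AUC when the learner yields scores).
#'
#' @param learner function `(X, y) -> model`; the model must support
#'   `predict(model, X, type = "class")` and optionally `type = "score"`.
#' @param X descriptor matrix.
#' @param y +1/-1 labels.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return A `classification_report` with attributes `predictions` and
#'   `fold` (pooled out-of-fold labels and fold ids).
#' @export
cross_validate <- function(learner, X, y, folds = 10L, seed = 1L) {
  n <- length(y)
  if (n < folds) mtq_stop("mtqsar_metric_error", "fewer records than folds")
  fold <- with_seed(seed, {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  # every training fold must contain both classes
  for (k in seq_len(folds)) {
    if (length(unique(y[fold != k])) < 2) {
      mtq_stop("mtqsar_metric_error",
               "a class is absent from a training fold; use fewer folds")
    }
  }
  pred <- integer(n)
  score <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    m <- learner(X[tr, , drop = FALSE], y[tr])
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE], type = "class")
    sc <- tryCatch(predict(m, X[!tr, , drop = FALSE], type = "score"),
                   error = function(e) NULL)
    if (!is.null(sc)) score[!tr] <- sc
  }
  auc <- if (!any(is.na(score))) roc_auc(score, y) else NULL
  rep <- classification_report(count_confusion(y, pred), auc = auc)
  attr(rep, "predictions") <- pred
  attr(rep, "fold") <- fold
  rep
}

#' Applicability domain by the standardisation approach
#'
#' Each query descriptor is standardised against the training mean and SD:
#' `s_ki = |x_ki - mu_k| / sigma_k`. A compound is inside the domain when
#' every `s_ki <= 3`; outside when even the smallest `s_ki > 3`;
#' otherwise the statistic `s* = mean_k(s_ki) + 1.28 sd_k(s_ki)` decides
#' (outside iff `s* > 3`). Zero-SD training descriptors are excluded with
#' a warning.
#'
#' @param X_train training descriptor matrix (the descriptors the model
#'   actually uses).
#' @param X_query query matrix over the same descriptors.
#' @param threshold the 3-sigma style threshold (default 3).
#' @param z the quantile multiplier in `s*` (default 1.28, the 90th
#'   percentile of the standard normal).
#' @return data.frame per query compound: `max_s`, `min_s`, `s_star`
#'   (NA when the max/min rule already decides) and logical `inside`.
#' @export
applicability_domain <- function(X_train, X_query, threshold = 3,
                                 z = 1.28) {
  X_train <- as.matrix(X_train)
  if (is.null(dim(X_query))) {
    X_query <- matrix(X_query, 1, dimnames = list(NULL, names(X_query)))
  }
  X_query <- as.matrix(X_query)
  if (!identical(colnames(X_train), colnames(X_query))) {
    if (is.null(colnames(X_train)) ||
        !all(colnames(X_train) %in% colnames(X_query))) {
      mtq_stop("mtqsar_metric_error", "descriptor mismatch between train and query")
    }
    X_query <- X_query[, colnames(X_train), drop = FALSE]
  }
  mu <- colMeans(X_train)
  sigma <- apply(X_train, 2, sd)
  keep <- sigma > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-SD descriptor(s) excluded from the AD", sum(!keep)),
            call. = FALSE)
  }
  if (!any(keep)) {
    mtq_stop("mtqsar_metric_error", "no descriptor with positive training SD")
  }
  S <- abs(sweep(X_query[, keep, drop = FALSE], 2, mu[keep])) /
    rep(sigma[keep], each = nrow(X_query))
  max_s <- apply(S, 1, max)
  min_s <- apply(S, 1, min)
  s_star <- rep(NA_real_, nrow(S))
  inside <- rep(NA, nrow(S))
  inside[max_s <= threshold] <- TRUE
  inside[min_s > threshold] <- FALSE
  und <- which(is.na(inside))
  if (length(und) > 0) {
    s_star[und] <- apply(S[und, , drop = FALSE], 1, function(s) {
      mean(s) + z * sd(s)
    })
    inside[und] <- s_star[und] <= threshold
  }
  data.frame(max_s = max_s, min_s = min_s, s_star = s_star,
             inside = inside)
}
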