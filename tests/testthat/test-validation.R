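test_that("classification reports reproduce published confusion-count metrics", {
  # linear model, test set: 310/316 actives, 510/580 inactives
  r <- classification_report(confusion_counts(TP = 310, FN = 6,
                                              TN = 510, FP = 70))
  expect_equal(round(r$sensitivity, 2), 98.10)
  expect_equal(round(r$specificity, 2), 87.93)
  expect_equal(round(r$accuracy, 2), 91.52)
  expect_equal(round(r$f_measure, 3), 0.891)
  expect_equal(round(r$mcc, 3), 0.832)
  # random forest, cross-validated sub-training set
  r2 <- classification_report(confusion_counts(TP = 1239, FN = 67,
                                               TN = 2209, FP = 70))
  expect_equal(round(r2$sensitivity, 2), 94.87)
  expect_equal(round(r2$specificity, 2), 96.93)
  expect_equal(round(r2$accuracy, 2), 96.18)
  expect_equal(round(r2$mcc, 3), 0.918)
  # perfect classifier
  rp <- classification_report(confusion_counts(50, 0, 80, 0))
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$specificity, 100)
  expect_equal(rp$accuracy, 100)
  expect_equal(rp$f_measure, 1)
  expect_equal(rp$mcc, 1)
})

test_that("MCC is swap-symmetric and safe at zero marginals", {
  r <- classification_report(confusion_counts(30, 8, 45, 12))
  r_swap <- classification_report(confusion_counts(45, 12, 30, 8))
  expect_equal(r$mcc, r_swap$mcc, tolerance = 1e-12)
  # all predictions negative: TP + FP = 0 marginal
  r0 <- classification_report(confusion_counts(0, 5, 9, 0))
  expect_equal(r0$mcc, 0)
  expect_equal(r0$f_measure, 0)
  expect_error(classification_report(confusion_counts(0, 0, 5, 1)),
               class = "mtqsar_metric_error")
})

test_that("rank-based AUC matches brute-force pair counting", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(-1, -1, 1, 1)), 1.0)
  expect_equal(roc_auc(c(10, 20, 1, 2), c(-1, -1, 1, 1)), 0.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(-1, 1, -1, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(1, -1), 5)), 0.5)
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    scores <- sample(rnorm(8), n, replace = TRUE)   # heavy ties
    labels <- sample(c(1L, -1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_brute(scores, labels))
  }
  skip_if_not_installed("pROC")
  set.seed(15)
  sc <- rnorm(80); lb <- sample(c(1L, -1L), 80, replace = TRUE)
  expect_equal(roc_auc(sc, lb),
               as.numeric(suppressMessages(pROC::auc(lb, sc))),
               tolerance = 1e-12)
})

test_that("cross-validation is stratified, pooled and deterministic", {
  set.seed(19)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- ifelse(runif(n) < plogis(2 * X[, 1]), 1L, -1L)
  learner <- function(Xt, yt) fit_lda(Xt, yt)
  r <- cross_validate(learner, X, y, folds = 10, seed = 3)
  fold <- attr(r, "fold")
  expect_equal(length(fold), n)
  expect_lte(diff(range(table(fold))), 2)   # class-wise balance, +/-1 per class
  # pooled counts cover every record exactly once
  cc <- r$counts
  expect_equal(cc$TP + cc$FN + cc$TN + cc$FP, n)
  r2 <- cross_validate(learner, X, y, folds = 10, seed = 3)
  expect_equal(attr(r2, "predictions"), attr(r, "predictions"))
  # leave-one-out runs and returns a report
  small <- 1:20
  rl <- cross_validate(learner, X[small, ], y[small],
                       folds = length(small), seed = 1)
  expect_s3_class(rl, "classification_report")
})

test_that("the applicability domain follows the standardisation rule", {
  # craft a training block with known mean and SD per descriptor
  set.seed(25)
  n <- 40
  Xt <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  mu <- colMeans(Xt); sg <- apply(Xt, 2, sd)
  q_at_s <- function(s) mu + s * sg    # query with chosen s-vector
  # query at the training mean: inside with all s = 0
  r0 <- applicability_domain(Xt, q_at_s(c(0, 0, 0)))
  expect_true(r0$inside); expect_equal(r0$max_s, 0, tolerance = 1e-9)
  # every s above the threshold: outside by the min rule
  r4 <- applicability_domain(Xt, q_at_s(c(4, 4, 4)))
  expect_false(r4$inside)
  expect_true(is.na(r4$s_star))
  # intermediate case decided by s* = mean + 1.28 sd
  r_mid <- applicability_domain(Xt, q_at_s(c(3.5, 0.1, 0.1)))
  expect_equal(r_mid$s_star, mean(c(3.5, 0.1, 0.1)) +
                 1.28 * sd(c(3.5, 0.1, 0.1)), tolerance = 1e-9)
  expect_equal(round(r_mid$s_star, 3), 3.746)
  expect_false(r_mid$inside)
  # an undecided case that stays inside (one mild excursion among many
  # well-behaved descriptors keeps s* below the threshold)
  Xt6 <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  q6 <- colMeans(Xt6) + c(3.05, 2, 2, 2, 2, 2) * apply(Xt6, 2, sd)
  r_in <- applicability_domain(Xt6, q6)
  expect_true(is.finite(r_in$s_star))
  expect_true(r_in$inside)
})

test_that("AD flags are invariant to consistent affine rescaling", {
  set.seed(26)
  Xt <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  Xq <- matrix(rnorm(20 * 4, sd = 2), 20, 4,
               dimnames = list(NULL, paste0("d", 1:4)))
  base <- applicability_domain(Xt, Xq)
  scale <- c(3, 0.2, 10, 1)
  shift <- c(-5, 2, 0, 100)
  tr <- function(X) sweep(sweep(X, 2, scale, "*"), 2, shift, "+")
  resc <- applicability_domain(tr(Xt), tr(Xq))
  expect_equal(resc$inside, base$inside)
  expect_equal(resc$max_s, base$max_s, tolerance = 1e-9)
})

test_that("zero-variance descriptors are excluded from the AD with a warning", {
  Xt <- cbind(a = rnorm(30), b = rep(1, 30))
  Xq <- cbind(a = c(0, 10), b = c(1, 5))
  expect_warning(r <- applicability_domain(Xt, Xq), "zero-SD")
  expect_equal(nrow(r), 2)
})
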