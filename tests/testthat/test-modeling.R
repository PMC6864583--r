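# two-class data generator with controllable separation
sim_classes <- function(n, p, delta = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, -1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  X[y == 1, 1] <- X[y == 1, 1] + delta
  list(X = X, y = y)
}

test_that("LDA fit statistics obey their identities", {
  for (seed in 1:3) {
    d <- sim_classes(120, 4, delta = 1.2, seed = seed)
    m <- fit_lda(d$X, d$y)
    s <- m$stats
    expect_gt(s$lambda, 0); expect_lte(s$lambda, 1)
    expect_equal(s$canonical_R, sqrt(1 - s$lambda), tolerance = 1e-9)
    expect_gte(s$chi_square, 0)
    expect_gte(s$mahalanobis_D2, 0)
    # lambda equals the within/total scatter determinant ratio
    X <- d$X; y <- d$y
    m1 <- colMeans(X[y == 1, ]); m2 <- colMeans(X[y == -1, ])
    W <- crossprod(sweep(X[y == 1, ], 2, m1)) +
      crossprod(sweep(X[y == -1, ], 2, m2))
    Tt <- crossprod(sweep(X, 2, colMeans(X)))
    expect_equal(s$lambda, det(W) / det(Tt), tolerance = 1e-8)
  }
})

test_that("degenerate and closed-form LDA cases behave as expected", {
  # identical class distributions: no separation
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  Xd <- rbind(X, X)
  yd <- rep(c(1L, -1L), each = 40)
  m <- fit_lda(Xd, yd)
  expect_equal(m$stats$lambda, 1, tolerance = 1e-9)
  expect_equal(m$stats$mahalanobis_D2, 0, tolerance = 1e-9)
  # 1-D two-group closed form: D2 = (2a)^2 / sigma2_pooled
  a <- 2; s <- 0.5
  X1 <- matrix(c(a - s, a + s, -a - s, -a + s), 4, 1,
               dimnames = list(NULL, "x"))
  y1 <- c(1L, 1L, -1L, -1L)
  m1 <- fit_lda(X1, y1)
  sigma2 <- (2 * s^2 + 2 * s^2) / 2   # pooled SS / (n - 2)
  expect_equal(m1$stats$mahalanobis_D2, (2 * a)^2 / sigma2,
               tolerance = 1e-9)
  # single-class input errors
  expect_error(fit_lda(X, rep(1L, 40)), class = "mtqsar_model_error")
})

test_that("LDA classification matches the pooled-Mahalanobis oracle and MASS", {
  for (p in c(2, 4, 6)) {
    d <- sim_classes(100, p, delta = 1.0, seed = p)   # balanced classes
    m <- fit_lda(d$X, d$y)
    pred <- classify_linear(m, d$X)
    expect_equal(pred, mahal_oracle(d$X, d$y, d$X))
    skip_if_not_installed("MASS")
    mm <- MASS::lda(d$X, grouping = factor(d$y))
    mp <- as.integer(as.character(predict(mm, d$X)$class))
    expect_equal(pred, mp)
  }
})

test_that("linear scoring reproduces the reference equation arithmetic", {
  model <- erk_reference_model()
  expect_equal(model$intercept, 1.653)
  expect_length(model$coefficients, 7)
  zero <- setNames(rep(0, 7), model$descriptors)
  expect_equal(unname(score_linear(model, zero)), 1.653)
  expect_equal(unname(classify_linear(model, zero)), 1L)
  # one descriptor moved: 1.653 + 18.180 * (-0.1) = -0.165
  x <- zero; x["D[Tssq11(CH)MN]me"] <- -0.1
  expect_equal(unname(score_linear(model, x)), 1.653 + 18.180 * (-0.1),
               tolerance = 1e-12)
  expect_equal(unname(classify_linear(model, x)), -1L)
  # doubling all coefficients and the intercept never changes the class
  doubled <- lda_model(2 * model$intercept, 2 * model$coefficients)
  set.seed(4)
  Q <- matrix(rnorm(50 * 7, sd = 10), 50, 7,
              dimnames = list(NULL, model$descriptors))
  expect_equal(classify_linear(doubled, Q), classify_linear(model, Q))
  # missing descriptors are an error
  expect_error(score_linear(model, c(`D[Tssq11(CH)MN]me` = 1)),
               class = "mtqsar_model_error")
})

test_that("GA selection finds planted descriptors and is elitist", {
  set.seed(99)
  n <- 300; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  eta <- 2 * X[, 7]
  y <- ifelse(runif(n) < plogis(eta), 1L, -1L)
  cfg <- ga_config(generations = 10, equation_length = 1,
                   initial_population = 20, selected_per_generation = 6,
                   seed = 1)
  hits <- 0
  for (s in 1:5) {
    cfg$seed <- s
    res <- ga_select(X, y, cfg, elimination_tol = NULL)
    if (identical(res$descriptors, "v7")) hits <- hits + 1
    # elitism: best fitness never worsens over generations
    expect_true(all(diff(res$fitness_trace) <= 1e-12))
  }
  expect_gte(hits, 4)
  # equation length equal to p selects all columns (no elimination)
  cfg_all <- ga_config(generations = 2, equation_length = 5,
                       initial_population = 6,
                       selected_per_generation = 2, seed = 2)
  res_all <- ga_select(X[, 1:5], y, cfg_all, elimination_tol = NULL)
  expect_setequal(res_all$descriptors, paste0("v", 1:5))
})

test_that("backward elimination shortens equations without hurting lambda", {
  set.seed(17)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- ifelse(runif(n) < plogis(2.5 * X[, 1]), 1L, -1L)
  cfg <- ga_config(generations = 8, equation_length = 5,
                   initial_population = 20, selected_per_generation = 6,
                   seed = 3)
  res <- ga_select(X, y, cfg, elimination_tol = 0.01)
  expect_lte(length(res$descriptors), 5)
  expect_true("v1" %in% res$descriptors)
  lam_full <- fit_lda(X, y)$stats$lambda
  expect_lte(res$model$stats$lambda, lam_full * 1.06)
})

test_that("duplicated informative columns are resolved by pre-treatment before GA", {
  set.seed(23)
  n <- 200
  x <- rnorm(n)
  X <- cbind(inf1 = x, inf2 = x, noise1 = rnorm(n), noise2 = rnorm(n))
  y <- ifelse(runif(n) < plogis(2 * x), 1L, -1L)
  Xp <- pretreat(X)
  expect_false("inf2" %in% colnames(Xp))   # exact duplicate dropped
  res <- ga_select(Xp, y, ga_config(generations = 5, equation_length = 1,
                                    initial_population = 10,
                                    selected_per_generation = 4, seed = 1),
                   elimination_tol = NULL)
  expect_equal(sum(res$descriptors %in% c("inf1", "inf2")), 1)
})

test_that("random forest honours its configuration and separates clean data", {
  d <- sim_classes(400, 6, delta = 3, seed = 5)
  m <- fit_rf(d$X, d$y, rf_config(seed = 11))
  pred <- predict(m, d$X, type = "class")
  expect_gte(mean(pred == d$y), 0.99)
  # deterministic under the seed
  m2 <- fit_rf(d$X, d$y, rf_config(seed = 11))
  expect_identical(predict(m2, d$X), pred)
  # mtry rule: int(log2(p) + 1)
  d128 <- sim_classes(60, 128, delta = 1, seed = 2)
  m128 <- fit_rf(d128$X, d128$y, rf_config(n_trees = 5, seed = 1))
  expect_equal(m128$mtry, 8L)
  # scores are active-vote fractions in [0, 1]
  sc <- predict(m, d$X, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("random forest out-of-bag and cross-validated accuracy agree", {
  set.seed(6)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- ifelse(runif(n) < plogis(1.5 * X[, 1] - X[, 2]), 1L, -1L)
  m <- fit_rf(X, y, rf_config(seed = 4))
  oob <- 100 * mean(as.integer(as.character(
    m$forest$predicted)) == y)
  cv <- cross_validate(function(Xt, yt) fit_rf(Xt, yt, rf_config(seed = 4)),
                       X, y, folds = 10, seed = 2)
  expect_lte(abs(oob - cv$accuracy), 5)
})

test_that("Y-randomisation degrades informative models and spares noise", {
  set.seed(13)
  n <- 250
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- ifelse(runif(n) < plogis(2.5 * X[, 1]), 1L, -1L)
  yr <- y_randomization(X, y, n_rand = 50, seed = 3)
  expect_length(yr$lambda_rand, 50)
  expect_gt(yr$lambda_rand_mean, yr$lambda_original)
  expect_gt(yr$lambda_rand_mean, 0.9)
  # pure noise: scrambling changes nothing systematically
  y_noise <- sample(c(1L, -1L), n, replace = TRUE)
  yr0 <- y_randomization(X, y_noise, n_rand = 50, seed = 3)
  expect_lt(abs(yr0$lambda_rand_mean - yr0$lambda_original), 0.05)
})

test_that("linear models survive the JSON round trip with averages", {
  d <- sim_classes(80, 3, delta = 1, seed = 8)
  m <- fit_lda(d$X, d$y)
  D <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("d1", "d2")))
  recs <- mk_records(40, seed = 4)
  avg <- build_all_condition_averages(D, recs)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(m, path, averages = avg, table_version = "1.0")
  back <- read_lda_model(path)
  expect_equal(back$model$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(back$model$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$model$stats$lambda, m$stats$lambda, tolerance = 1e-12)
  expect_equal(back$averages$bt$means, avg$bt$means, tolerance = 1e-12)
})
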