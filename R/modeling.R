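#' Linear discriminant model with QSAR fit statistics
#'
#' Two-class Fisher discriminant expressed as an intercept plus
#' coefficients over deviation descriptors, the form in which linear
#' mt-QSAR classification equations are reported. Alongside the
#' coefficients the fit carries the classical discriminant statistics:
#' Wilks' lambda (|W|/|T|, within- over total-scatter determinants),
#' canonical R = sqrt(1 - lambda), Bartlett's chi-square
#' -(n - 1 - (p + g)/2) ln(lambda), the squared Mahalanobis distance
#' between class centroids under the pooled covariance, and the two-group
#' F transformation of lambda.
#'
#' Scoring convention: actives (+1) score positive; `classify = sign`.
#' Class priors (training frequencies) enter the intercept.
#'
#' @param X numeric matrix of descriptors (rows = records).
#' @param y labels in {+1, -1}; both classes must be present.
#' @param ridge added to the pooled covariance diagonal if it is singular.
#' @return An `lda_model` with elements `intercept`, `coefficients`
#'   (named), `stats` (lambda, canonical_R, chi_square, mahalanobis_D2,
#'   fisher_F, p_value), `descriptors`, `n`, `priors`.
#' @export
fit_lda <- function(X, y, ridge = 1e-8) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) {
    mtq_stop("mtqsar_model_error", "labels must be +1/-1")
  }
  if (length(unique(y)) < 2) {
    mtq_stop("mtqsar_model_error", "both classes must be present")
  }
  n <- nrow(X); p <- ncol(X); g <- 2L
  i1 <- y == 1L; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  mall <- colMeans(X)
  W <- crossprod(sweep(X[i1, , drop = FALSE], 2, m1)) +
    crossprod(sweep(X[i2, , drop = FALSE], 2, m2))
  Tt <- crossprod(sweep(X, 2, mall))
  Sp <- W / (n - g)
  inv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(inv)) {
    # scale-aware ridge, escalated until the system is solvable
    scale <- mean(diag(Sp)); if (!is.finite(scale) || scale <= 0) scale <- 1
    r <- ridge
    while (is.null(inv) && r <= 1e-2) {
      inv <- tryCatch(solve(Sp + diag(r * scale, p)),
                      error = function(e) NULL)
      r <- r * 100
    }
    if (is.null(inv)) {
      mtq_stop("mtqsar_model_error", "singular pooled covariance")
    }
  }
  dm <- m1 - m2
  D2 <- drop(t(dm) %*% inv %*% dm)
  # Wilks lambda via the Hotelling T2 identity (robust for any p):
  # lambda = 1 / (1 + (n1 n2)/(n (n-2)) * D2)
  lambda <- 1 / (1 + (n1 * n2) / (n * (n - g)) * D2)
  chi2 <- -(n - 1 - (p + g) / 2) * log(lambda)
  Fstat <- ((1 - lambda) / lambda) * ((n - p - 1) / p)
  pval <- pf(Fstat, p, n - p - 1, lower.tail = FALSE)
  w <- drop(inv %*% dm)
  intercept <- -sum(w * (m1 + m2) / 2) + log(n1 / n2)
  model <- structure(list(
    intercept = intercept,
    coefficients = setNames(w, colnames(X)),
    descriptors = colnames(X),
    stats = list(lambda = lambda, canonical_R = sqrt(1 - lambda),
                 chi_square = chi2, mahalanobis_D2 = D2,
                 fisher_F = Fstat, p_value = pval),
    n = n, priors = c(active = n1 / n, inactive = n2 / n),
    fingerprint = list(n = n, p = p, n_active = n1)),
    class = "lda_model")
  model
}

#' Construct an `lda_model` from known coefficients
#'
#' Used to encode published classification equations directly.
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector over deviation descriptors.
#' @param stats optional list of fit statistics.
#' @return An `lda_model`.
#' @export
lda_model <- function(intercept, coefficients, stats = NULL) {
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 descriptors = names(coefficients),
                 stats = stats, n = NA_integer_, priors = NULL,
                 fingerprint = NULL),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: %d descriptor(s)>\n", length(x$coefficients)))
  eq <- paste(sprintf("%+.4g %s", x$coefficients, x$descriptors),
              collapse = " ")
  cat(sprintf("  score = %.4g %s\n", x$intercept, eq))
  if (!is.null(x$stats)) {
    cat(sprintf("  lambda = %.4g, canonical R = %.4g, chi2 = %.4g, D2 = %.4g\n",
                x$stats$lambda, x$stats$canonical_R, x$stats$chi_square,
                x$stats$mahalanobis_D2))
  }
  invisible(x)
}

#' Linear score and classification
#'
#' `score = intercept + sum(coef * x)`; the predicted class is +1 when the
#' score is strictly positive, else -1.
#'
#' @param model an `lda_model`.
#' @param X matrix or data.frame covering all model descriptors (extra
#'   columns ignored), or a single named vector.
#' @return Numeric scores (`score_linear`) or +1/-1 labels
#'   (`classify_linear`).
#' @export
score_linear <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  miss <- setdiff(model$descriptors, colnames(X))
  if (length(miss) > 0) {
    mtq_stop("mtqsar_model_error", paste(
      "missing model descriptor(s):", paste(miss, collapse = ", ")))
  }
  drop(model$intercept +
         X[, model$descriptors, drop = FALSE] %*% model$coefficients)
}

#' @rdname score_linear
#' @export
classify_linear <- function(model, X) {
  ifelse(score_linear(model, X) > 0, 1L, -1L)
}

#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  if (type == "score") score_linear(object, newdata)
  else classify_linear(object, newdata)
}

#' Genetic-algorithm configuration for descriptor selection
#'
#' @param generations,equation_length,mutation_prob,initial_population,selected_per_generation
#'   GA settings (defaults: 100 generations, fixed equation length 10,
#'   per-gene mutation 0.3, 100 initial equations, 30 selected per
#'   generation).
#' @param seed RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(generations = 100L, equation_length = 10L,
                      mutation_prob = 0.3, initial_population = 100L,
                      selected_per_generation = 30L, seed = 1L) {
  stopifnot(generations >= 1, equation_length >= 1,
            initial_population >= 2,
            selected_per_generation >= 1,
            selected_per_generation <= initial_population,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(generations = as.integer(generations),
                 equation_length = as.integer(equation_length),
                 mutation_prob = mutation_prob,
                 initial_population = as.integer(initial_population),
                 selected_per_generation = as.integer(selected_per_generation),
                 seed = seed),
            class = "ga_config")
}

#' GA-LDA descriptor subset selection
#'
#' Evolves a population of fixed-length descriptor subsets; fitness is the
#' Wilks lambda of the candidate LDA (minimised). Elitist selection keeps
#' the top `selected_per_generation` equations each generation; offspring
#' arise by uniform crossover of two random parents followed by per-gene
#' mutation. After the GA, backward elimination drops terms whose removal
#' worsens lambda by no more than `elimination_tol` (relative), which
#' reconciles the fixed GA equation length with shorter reported
#' equations.
#'
#' @param X deviation-descriptor matrix.
#' @param y +1/-1 labels.
#' @param cfg a [ga_config()].
#' @param elimination_tol relative lambda tolerance of the backward
#'   elimination step (default 0.01; `NULL` disables it).
#' @return list with `model` (fitted `lda_model`), `descriptors`,
#'   `fitness_trace` (best lambda per generation) and `cfg`.
#' @export
ga_select <- function(X, y, cfg = ga_config(), elimination_tol = 0.01) {
  X <- as.matrix(X)
  p <- ncol(X)
  L <- cfg$equation_length
  if (p < L) {
    mtq_stop("mtqsar_model_error",
             "fewer descriptors than the GA equation length")
  }
  fit_cache <- new.env(parent = emptyenv())
  fitness <- function(subset) {
    key <- paste(subset, collapse = ",")
    hit <- fit_cache[[key]]
    if (!is.null(hit)) return(hit)
    lam <- tryCatch(
      fit_lda(X[, subset, drop = FALSE], y)$stats$lambda,
      error = function(e) 1)
    fit_cache[[key]] <- lam
    lam
  }
  res <- with_seed(cfg$seed, {
    pop <- replicate(cfg$initial_population,
                     sort(sample.int(p, L)), simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
    trace <- numeric(cfg$generations)
    best <- pop[[which.min(fit)]]; best_fit <- min(fit)
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(cfg$selected_per_generation)]]
      elite_fit <- fit[ord[seq_len(cfg$selected_per_generation)]]
      n_off <- cfg$initial_population - cfg$selected_per_generation
      off <- vector("list", n_off)
      resample <- function(x, size) x[sample.int(length(x), size)]
      for (o in seq_len(n_off)) {
        pa <- elite[[sample.int(length(elite), 1)]]
        pb <- elite[[sample.int(length(elite), 1)]]
        pool <- unique(c(pa, pb))
        child <- if (length(pool) >= L) resample(pool, L) else
          c(pool, resample(setdiff(seq_len(p), pool), L - length(pool)))
        mut <- which(runif(L) < cfg$mutation_prob)
        avail <- setdiff(seq_len(p), child)
        if (length(mut) > 0 && length(avail) > 0) {
          mut <- mut[seq_len(min(length(mut), length(avail)))]
          child[mut] <- resample(avail, length(mut))
        }
        off[[o]] <- sort(unique(child))
        # repair duplicates introduced by crossover/mutation
        while (length(off[[o]]) < L) {
          off[[o]] <- sort(c(off[[o]],
                             resample(setdiff(seq_len(p), off[[o]]),
                                      L - length(off[[o]]))))
        }
      }
      pop <- c(elite, off)
      fit <- c(elite_fit, vapply(off, fitness, numeric(1)))
      if (min(fit) < best_fit) {
        best_fit <- min(fit); best <- pop[[which.min(fit)]]
      }
      trace[gen] <- best_fit
    }
    list(best = best, trace = trace)
  })
  subset <- res$best
  if (!is.null(elimination_tol)) {
    subset <- with_seed(cfg$seed + 1L,
                        backward_eliminate(X, y, subset, elimination_tol))
  }
  model <- fit_lda(X[, subset, drop = FALSE], y)
  list(model = model, descriptors = colnames(X)[subset],
       fitness_trace = res$trace, cfg = cfg)
}

# Drop terms whose removal does not worsen lambda by more than tol
# (relative), one at a time, greedily.
backward_eliminate <- function(X, y, subset, tol) {
  lam <- fit_lda(X[, subset, drop = FALSE], y)$stats$lambda
  repeat {
    if (length(subset) <= 1) break
    lams <- vapply(seq_along(subset), function(d) {
      tryCatch(fit_lda(X[, subset[-d], drop = FALSE], y)$stats$lambda,
               error = function(e) Inf)
    }, numeric(1))
    d <- which.min(lams)
    if (lams[d] <= lam * (1 + tol)) {
      subset <- subset[-d]
      lam <- fit_lda(X[, subset, drop = FALSE], y)$stats$lambda
    } else break
  }
  subset
}

#' Random forest configuration
#'
#' @param n_trees number of trees (default 100).
#' @param bag_fraction bootstrap bag size as a fraction of n (default 1).
#' @param max_depth unlimited when `Inf` (default).
#' @param features_per_split candidate features per split; `NULL` means
#'   `int(log2(p) + 1)`.
#' @param seed RNG seed.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 100L, bag_fraction = 1.0, max_depth = Inf,
                      features_per_split = NULL, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 bag_fraction = bag_fraction, max_depth = max_depth,
                 features_per_split = features_per_split, seed = seed),
            class = "rf_config")
}

#' Fit a random forest classifier
#'
#' A thin deterministic wrapper around `randomForest` with the settings
#' used for mt-QSAR modelling: `n_trees` trees, bootstrap bags of size n,
#' unlimited depth and `int(log2(p) + 1)` candidate features per split
#' (Gini criterion). Prediction is by majority vote; the score is the
#' active-vote fraction.
#'
#' @param X descriptor matrix.
#' @param y +1/-1 labels.
#' @param cfg an [rf_config()].
#' @return An `rf_model` wrapping the forest.
#' @export
fit_rf <- function(X, y, cfg = rf_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    mtq_stop("mtqsar_model_error", "both classes must be present")
  }
  p <- ncol(X)
  mtry <- cfg$features_per_split %||% as.integer(floor(log2(p) + 1))
  mtry <- max(1L, min(mtry, p))
  yf <- factor(y, levels = c(-1L, 1L))
  fit <- with_seed(cfg$seed, randomForest::randomForest(
    x = X, y = yf, ntree = cfg$n_trees, mtry = mtry,
    sampsize = max(1L, round(cfg$bag_fraction * nrow(X))),
    replace = TRUE,
    nodesize = 1,
    maxnodes = if (is.finite(cfg$max_depth)) 2^cfg$max_depth else NULL))
  structure(list(forest = fit, descriptors = colnames(X), cfg = cfg,
                 mtry = mtry),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$descriptors, drop = FALSE]
  votes <- unname(predict(object$forest, X, type = "prob")[, "1"])
  if (type == "score") return(votes)
  # majority vote with a deterministic tie-break (exact 50/50 votes are
  # called inactive); randomForest's own response type breaks ties
  # randomly, which would make screening runs irreproducible
  ifelse(votes > 0.5, 1L, -1L)
}

#' Y-randomisation test
#'
#' Labels are randomly scrambled `n_rand` times and the model refitted on
#' the SAME descriptor subset each time; a real structure-activity signal
#' shows as the scrambled Wilks lambdas staying close to 1 while the
#' original lambda is much smaller.
#'
#' @param X descriptor matrix restricted to the model's descriptors.
#' @param y original +1/-1 labels.
#' @param n_rand number of scrambles (default 100).
#' @param seed RNG seed.
#' @return list with `lambda_original`, `lambda_rand_mean` and
#'   `lambda_rand` (all `n_rand` values).
#' @export
y_randomization <- function(X, y, n_rand = 100L, seed = 1L) {
  lam0 <- fit_lda(X, y)$stats$lambda
  lams <- with_seed(seed, vapply(seq_len(n_rand), function(r) {
    ys <- sample(y)
    tryCatch(fit_lda(X, ys)$stats$lambda, error = function(e) NA_real_)
  }, numeric(1)))
  list(lambda_original = lam0,
       lambda_rand_mean = mean(lams, na.rm = TRUE),
       lambda_rand = lams)
}

#' Serialise / load a linear model as JSON
#'
#' The JSON bundle records intercept, coefficients, fit statistics and,
#' when supplied, the frozen condition averages and property-table
#' version, so a saved model is a self-contained screening artefact.
#'
#' @param model an `lda_model`.
#' @param path JSON path.
#' @param averages optional condition averages to embed.
#' @param table_version property-table version string.
#' @return `path` invisibly; `read_lda_model` returns a list with
#'   `model` and (when embedded) `averages`.
#' @export
write_lda_model <- function(model, path, averages = NULL,
                            table_version = NULL) {
  enc <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              stats = model$stats,
              n = model$n,
              table_version = table_version)
  if (!is.null(averages)) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    write_condition_averages(averages, tmp)
    enc$averages <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- lda_model(intercept = enc$intercept,
                     coefficients = unlist(enc$coefficients),
                     stats = as.list(enc$stats))
  model$n <- enc$n %||% NA_integer_
  out <- list(model = model)
  if (!is.null(enc$averages)) {
    tmp <- tempfile(); on.exit(unlink(tmp))
    jsonlite::write_json(enc$averages, tmp, auto_unbox = TRUE, digits = NA)
    out$averages <- read_condition_averages(tmp)
  }
  out
}

#' The published ERK-1/2 linear discriminant equation
#'
#' Loads the bundled seven-descriptor linear classification equation for
#' ERK-1/2 inhibition (intercept 1.653; deviation descriptors over charge,
#' polarizability, polar surface area, van der Waals volume and
#' hydrophobicity quadratic indices) together with its reported fit
#' statistics. Useful as a worked example and as a fixed reference model
#' for scoring.
#'
#' @return An `lda_model`.
#' @export
erk_reference_model <- function() {
  path <- system.file("extdata", "erk_lda_model.json", package = "mtqsar")
  read_lda_model(path)$model
}
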