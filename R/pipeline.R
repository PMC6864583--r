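#' End-to-end mt-QSAR pipeline
#'
#' Runs the full workflow on a condition-annotated dataset: descriptor
#' computation, activity labelling, k-means cluster division into
#' modelling and external validation sets, descriptor pre-treatment,
#' Box-Jenkins deviation descriptors frozen on the sub-training actives,
#' GA-LDA and random-forest model fitting, the validation battery
#' (test-set and external-set reports, ten-fold cross-validation,
#' Y-randomisation, applicability domain), ring-fragment contribution
#' scoring and consensus virtual screening of a library.
#'
#' @param config a [pipeline_config()].
#' @return A list of stage artefacts (see Details); when
#'   `config$out_dir` is set, models, reports and a reproducibility
#'   manifest are also written there.
#' @details The returned list contains `split`, `lda` (GA-LDA result),
#'   `rf`, `reports` (named classification reports), `y_rand`, `ad`,
#'   `fragments`, `screening`, `averages`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_start <- Sys.time()
  log_stage <- function(...) {
    if (config$verbose) message(sprintf("[%s] %s",
                                        format(Sys.time(), "%H:%M:%S"),
                                        sprintf(...)))
  }
  dataset <- config$dataset
  if (is.null(dataset)) {
    log_stage("generating synthetic dataset (n = %d compounds)",
              config$synthetic_spec$n_compounds)
    dataset <- generate_dataset(config$synthetic_spec)
  }
  records <- dataset$records
  graphs <- dataset$graphs
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      mtq_stop("mtqsar_pipeline_error", sprintf(
        "stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  log_stage("computing descriptors for %d compounds", length(graphs))
  D_cmp <- stage("descriptors",
                 compute_descriptor_matrix(graphs, config$descriptor_config))
  D <- D_cmp[match(records$id, rownames(D_cmp)), , drop = FALSE]
  rownames(D) <- NULL
  y <- records$label

  log_stage("k-MCA split over %d records", nrow(D))
  split <- stage("kmca_split", kmca_split(
    D, y, k = config$kmca_k, max_iter = config$kmca_max_iter,
    validation_fraction = config$validation_fraction,
    seed = config$seed))
  ss <- stage("sub_split", sub_split(split$modelling,
                                     train_fraction = config$train_fraction,
                                     seed = config$seed + 1L))
  split$sub_training <- ss$sub_training
  split$test <- ss$test

  log_stage("pre-treating %d descriptors", ncol(D))
  D_pre <- stage("pretreat", {
    kept <- pretreat(D[split$modelling, , drop = FALSE],
                     var_min = config$var_min, r2_max = config$r2_max)
    D[, colnames(kept), drop = FALSE]
  })

  log_stage("Box-Jenkins deviations (%d raw descriptors)", ncol(D_pre))
  averages <- stage("box_jenkins", build_all_condition_averages(
    D_pre[split$sub_training, , drop = FALSE],
    records[split$sub_training, , drop = FALSE]))
  Dd <- stage("box_jenkins",
              deviation_descriptors(D_pre, averages, records))

  idx_tr <- split$sub_training
  idx_te <- split$test
  idx_val <- split$validation

  log_stage("GA-LDA selection over %d deviation descriptors", ncol(Dd))
  ga <- stage("ga_lda", ga_select(Dd[idx_tr, , drop = FALSE], y[idx_tr],
                                  cfg = config$ga_config))
  lda_m <- ga$model

  log_stage("random forest (%d trees)", config$rf_config$n_trees)
  rf_m <- stage("rf", fit_rf(Dd[idx_tr, , drop = FALSE], y[idx_tr],
                             cfg = config$rf_config))

  log_stage("validation battery")
  reports <- list()
  for (mm in list(list(name = "lda", model = lda_m,
                       X = Dd[, ga$descriptors, drop = FALSE]),
                  list(name = "rf", model = rf_m, X = Dd))) {
    for (part in list(list(name = "sub_training", idx = idx_tr),
                      list(name = "test", idx = idx_te),
                      list(name = "external", idx = idx_val))) {
      Xp <- mm$X[part$idx, , drop = FALSE]
      pr <- predict(mm$model, Xp, type = "class")
      sc <- predict(mm$model, Xp, type = "score")
      reports[[paste(mm$name, part$name, sep = "_")]] <-
        classification_report(count_confusion(y[part$idx], pr),
                              auc = roc_auc(sc, y[part$idx]))
    }
  }
  reports$lda_cv <- stage("cross_validation", cross_validate(
    function(X, yy) fit_lda(X, yy),
    Dd[idx_tr, ga$descriptors, drop = FALSE], y[idx_tr],
    folds = config$cv_folds, seed = config$seed + 2L))
  yr <- stage("y_randomization", y_randomization(
    Dd[idx_tr, ga$descriptors, drop = FALSE], y[idx_tr],
    n_rand = config$n_y_rand, seed = config$seed + 3L))
  ad <- stage("applicability_domain", {
    tr <- Dd[idx_tr, ga$descriptors, drop = FALSE]
    list(test = applicability_domain(tr, Dd[idx_te, ga$descriptors,
                                            drop = FALSE]),
         external = applicability_domain(tr, Dd[idx_val, ga$descriptors,
                                                drop = FALSE]))
  })

  log_stage("fragment analysis")
  fragments <- stage("fragments", {
    fr <- enumerate_ring_fragments(graphs,
                                   min_compounds = config$min_fragment_compounds)
    if (nrow(fr) >= 2) {
      raw <- fragment_scores(fr, lda_m, config$conditions, averages,
                             cfg = config$descriptor_config)
      list(fragments = fr, raw = raw, std = standardize_scores(raw))
    } else list(fragments = fr, raw = NULL, std = NULL)
  })

  screening <- NULL
  if (config$n_library > 0) {
    log_stage("virtual screening of %d library compounds", config$n_library)
    screening <- stage("screening", {
      lib <- generate_molecules(config$n_library,
                                seed = config$seed + 4L, ids = "lib")
      screen_library(lib, rf_m, config$conditions, averages,
                     cfg = config$descriptor_config,
                     ad_train = Dd[idx_tr, ga$descriptors, drop = FALSE])
    })
  }

  manifest <- list(
    n_compounds = length(graphs), n_records = nrow(records),
    n_descriptors_raw = ncol(D), n_descriptors_pretreated = ncol(D_pre),
    n_deviation_descriptors = ncol(Dd),
    lda_descriptors = ga$descriptors,
    table_version = attr(D_cmp, "table_version"),
    descriptor_config = unclass(config$descriptor_config),
    seed = config$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  out <- list(split = split, lda = ga, rf = rf_m, reports = reports,
              y_rand = yr, ad = ad, fragments = fragments,
              screening = screening, averages = averages,
              records = records, deviations = Dd, manifest = manifest)
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(out, config)
  }
  log_stage("pipeline finished in %.1f s", manifest$elapsed_s)
  out
}

#' Pipeline configuration
#'
#' @param dataset a dataset as returned by [generate_dataset()] (or a
#'   compatible list with `records` and `graphs`); when `NULL`, a
#'   synthetic dataset is generated from `synthetic_spec`.
#' @param synthetic_spec generator spec used when `dataset` is `NULL`.
#' @param descriptor_config a [quadratic_config()].
#' @param conditions condition table for fragments/screening.
#' @param kmca_k,kmca_max_iter,validation_fraction k-MCA division
#'   settings.
#' @param train_fraction sub-training share of the modelling set.
#' @param var_min,r2_max pre-treatment thresholds.
#' @param ga_config,rf_config learner settings.
#' @param cv_folds cross-validation folds.
#' @param n_y_rand Y-randomisation scrambles.
#' @param min_fragment_compounds fragment frequency threshold.
#' @param n_library size of the generated screening library (0 skips
#'   screening).
#' @param seed master seed; stage seeds are derived as seed + 1, ...
#' @param out_dir artefact directory (`NULL` = return results only).
#' @param verbose log stage progress.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = NULL,
                            synthetic_spec = mtqsar::synthetic_spec(),
                            descriptor_config = quadratic_config(),
                            conditions = default_conditions(),
                            kmca_k = 10L, kmca_max_iter = 500L,
                            validation_fraction = 0.30,
                            train_fraction = 0.8,
                            var_min = 0.001, r2_max = 0.85,
                            ga_config = mtqsar::ga_config(),
                            rf_config = mtqsar::rf_config(),
                            cv_folds = 10L, n_y_rand = 100L,
                            min_fragment_compounds = 15L,
                            n_library = 100L,
                            seed = 1L, out_dir = NULL, verbose = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_pipeline_artifacts <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$out_dir, ...)
  write_lda_model(out$lda$model, fp("lda_model.json"),
                  averages = out$averages,
                  table_version = out$manifest$table_version)
  write_split(out$split, fp("split.json"))
  rep_enc <- lapply(out$reports, function(r) {
    c(r[c("sensitivity", "specificity", "accuracy", "f_measure", "mcc")],
      list(auc = r$auc, counts = unclass(r$counts)))
  })
  jsonlite::write_json(rep_enc, fp("reports.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    list(lambda_original = out$y_rand$lambda_original,
         lambda_rand_mean = out$y_rand$lambda_rand_mean),
    fp("y_randomization.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(out$fragments$std)) {
    write_fragment_report(out$fragments$std, fp("fragments.csv"))
  }
  if (!is.null(out$screening)) {
    write_screening_result(out$screening, fp("screening.csv"))
  }
  jsonlite::write_json(out$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
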