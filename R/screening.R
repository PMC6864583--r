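#' Multi-condition virtual screening and drug-likeness
#'
#' @name screening
NULL

#' Lipinski rule-of-five properties
#'
#' MW includes implicit hydrogens; donors are N/O atoms bearing at least
#' one hydrogen; acceptors are all N and O atoms (classical rule-of-five
#' counting); ALOGP is the sum of the atomic hydrophobicity contributions
#' from the HYD table. Pass requires MW < 500 Da, nHDon <= 5,
#' nHAcc <= 10 and ALOGP < 5.
#'
#' @param g a `mol_graph`.
#' @param tables property table set.
#' @return list with `MW`, `nHDon`, `nHAcc`, `ALOGP`, `pass`.
#' @export
lipinski_properties <- function(g, tables = load_property_tables()) {
  P <- assign_properties(g, tables, properties = c("HYD", "M"))
  h_mass <- lookup_property(tables$tables$M, "M", "H", "*", 0L)
  mw <- sum(P[, "M"]) + sum(g$atoms$nH) * h_mass
  is_no <- g$atoms$element %in% c("N", "O")
  nhdon <- sum(is_no & g$atoms$nH >= 1)
  nhacc <- sum(is_no)
  alogp <- sum(P[, "HYD"])
  list(MW = mw, nHDon = nhdon, nHAcc = nhacc, ALOGP = alogp,
       pass = mw < 500 && nhdon <= 5 && nhacc <= 10 && alogp < 5)
}

#' Screen a compound library under multiple experimental conditions
#'
#' Every library compound is virtually assayed under each experimental
#' condition: its raw descriptors are converted to condition-deviation
#' descriptors with the frozen training averages and pushed through the
#' classifier. Consensus hits are the compounds predicted active under
#' every screened condition. Applicability-domain flags and Lipinski
#' properties are annotated per compound; AD outliers are reported, not
#' removed.
#'
#' @param graphs list of library `mol_graph`s.
#' @param model an `lda_model` or `rf_model`.
#' @param conditions data.frame from [default_conditions()] (or a subset).
#' @param averages frozen condition averages (list with `bt`, `me`).
#' @param cfg descriptor configuration used at training time.
#' @param ad_train optional training deviation-descriptor matrix
#'   (restricted to the model's descriptors) enabling AD annotation.
#' @param tables property table set.
#' @return A `screening_result` list: `predictions` (compounds x
#'   conditions of +1/-1), `scores`, `ad_inside` (or NULL), `consensus`
#'   (logical), `lipinski` (data.frame), `counts` (cases, positives,
#'   hits).
#' @export
screen_library <- function(graphs, model, conditions, averages,
                           cfg = quadratic_config(), ad_train = NULL,
                           tables = load_property_tables()) {
  D <- compute_descriptor_matrix(graphs, cfg, tables = tables)
  want <- colnames(averages[[1]]$means)
  miss <- setdiff(want, colnames(D))
  if (length(miss) > 0) {
    mtq_stop("mtqsar_model_error", paste(
      "library descriptors missing under this config:",
      paste(head(miss, 3), collapse = ", ")))
  }
  D <- D[, want, drop = FALSE]
  ids <- rownames(D)
  nC <- nrow(conditions)
  pred <- matrix(NA_integer_, nrow(D), nC,
                 dimnames = list(ids, conditions$condition))
  score <- matrix(NA_real_, nrow(D), nC,
                  dimnames = list(ids, conditions$condition))
  ad_in <- if (!is.null(ad_train)) pred * NA else NULL
  for (ci in seq_len(nC)) {
    recs <- data.frame(bt = rep(conditions$bt[ci], nrow(D)),
                       me = rep(conditions$me[ci], nrow(D)))
    Dd <- deviation_descriptors(D, averages, recs)
    pred[, ci] <- predict(model, Dd, type = "class")
    score[, ci] <- predict(model, Dd, type = "score")
    if (!is.null(ad_train)) {
      dsc <- colnames(ad_train)
      ad <- applicability_domain(ad_train, Dd[, dsc, drop = FALSE])
      ad_in[, ci] <- ad$inside
    }
  }
  consensus <- apply(pred == 1L, 1, all)
  lip <- do.call(rbind, lapply(graphs, function(g) {
    as.data.frame(lipinski_properties(g, tables))
  }))
  rownames(lip) <- ids
  structure(list(predictions = pred, scores = score,
                 ad_inside = ad_in, consensus = consensus,
                 lipinski = lip,
                 counts = list(cases = length(pred),
                               positives = sum(pred == 1L),
                               hits = sum(consensus))),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result: %d compounds x %d conditions = %d cases; %d positive predictions; %d consensus hit(s)>\n",
    nrow(x$predictions), ncol(x$predictions), x$counts$cases,
    x$counts$positives, x$counts$hits))
  invisible(x)
}

#' Write screening results to CSV (one row per compound)
#'
#' @param result a `screening_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_result <- function(result, path) {
  df <- data.frame(id = rownames(result$predictions),
                   result$predictions,
                   consensus_hit = result$consensus,
                   result$lipinski, check.names = FALSE)
  if (!is.null(result$ad_inside)) {
    adf <- result$ad_inside
    colnames(adf) <- paste0("ad_inside_", colnames(adf))
    df <- cbind(df, adf)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
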