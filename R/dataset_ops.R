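#' Dataset curation, division and descriptor pre-treatment
#'
#' @name dataset-ops
NULL

#' Remove duplicate (structure, condition) records
#'
#' At most one record per (canonical structure, bt, me) is kept; ties are
#' resolved by keeping the most potent (lowest nM) measurement.
#'
#' @param records data.frame with at least `smiles` (or a precomputed
#'   `structure_key`), `bt`, `me`, `activity_nM`.
#' @param graphs optional list of parsed `mol_graph` aligned with the
#'   records, used to derive canonical structure keys; when absent the raw
#'   SMILES string is the key.
#' @return The deduplicated records (original row order preserved), with a
#'   `removed` attribute reporting dropped row indices.
#' @export
deduplicate <- function(records, graphs = NULL) {
  if (nrow(records) == 0) {
    attr(records, "removed") <- integer()
    return(records)
  }
  key <- if (!is.null(records$structure_key)) {
    as.character(records$structure_key)
  } else if (!is.null(graphs)) {
    vapply(graphs, canonical_smiles, character(1))
  } else {
    as.character(records$smiles)
  }
  full <- paste(key, records$bt, records$me, sep = "\r")
  ord <- order(records$activity_nM)   # most potent first
  keep_first <- ord[!duplicated(full[ord])]
  keep <- sort(keep_first)
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- setdiff(seq_len(nrow(records)), keep)
  out
}

#' k-means cluster analysis division into modelling and validation sets
#'
#' Descriptors are z-standardised, the class label appended as one extra
#' standardised coordinate, and k-means (Euclidean) run with `k` clusters;
#' from every cluster, `round(validation_fraction * size)` records are
#' sampled without replacement into the external validation set. The
#' remainder is the modelling set.
#'
#' @param D descriptor matrix (records x descriptors).
#' @param labels +1/-1 class labels aligned with `D`.
#' @param k number of clusters (default 10).
#' @param max_iter k-means iteration cap (default 500).
#' @param validation_fraction fraction sampled per cluster (default 0.30).
#' @param seed RNG seed.
#' @return A `split_result` list: `modelling`, `validation` (row indices),
#'   `clusters`, `seed`, and the parameters.
#' @export
kmca_split <- function(D, labels, k = 10L, max_iter = 500L,
                       validation_fraction = 0.30, seed = 1L) {
  n <- nrow(D)
  if (n < k) mtq_stop("mtqsar_split_error", "fewer records than clusters")
  Z <- standardise_columns(cbind(D, label = as.numeric(labels)))
  cl <- with_seed(seed, {
    fit <- NULL
    for (attempt in 1:10) {
      fit <- tryCatch(kmeans(Z, centers = k, iter.max = max_iter),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      mtq_stop("mtqsar_split_error", "k-means failed after 10 restarts")
    }
    fit$cluster
  })
  validation <- with_seed(seed + 1L, {
    val <- integer()
    for (cid in sort(unique(cl))) {
      members <- which(cl == cid)
      take <- round(validation_fraction * length(members))
      if (take > 0) {
        val <- c(val, sort(sample(members, take)))
      }
    }
    sort(val)
  })
  structure(list(modelling = setdiff(seq_len(n), validation),
                 validation = validation, clusters = cl,
                 k = k, validation_fraction = validation_fraction,
                 seed = seed),
            class = "split_result")
}

standardise_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

#' Random sub-training / test division of the modelling set
#'
#' @param modelling integer indices of the modelling set.
#' @param train_fraction sub-training share (default 0.8).
#' @param seed RNG seed.
#' @return list with `sub_training` and `test` index vectors
#'   (sizes `round(f * n)` and the remainder).
#' @export
sub_split <- function(modelling, train_fraction = 0.8, seed = 1L) {
  n <- length(modelling)
  if (n < 5) mtq_stop("mtqsar_split_error", "modelling set too small")
  n_tr <- round(train_fraction * n)
  tr <- with_seed(seed, sort(sample(modelling, n_tr)))
  list(sub_training = tr, test = setdiff(modelling, tr))
}

#' Serialise a split for exact re-runs
#' @param split a `split_result` (optionally with `sub_training`/`test`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split[setdiff(names(split), "clusters")], path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Descriptor pre-treatment
#'
#' Drops near-constant columns (variance below `var_min`), then scans
#' column pairs in canonical (left-to-right) order and drops the later
#' column of any pair whose squared Pearson correlation exceeds `r2_max`.
#' Idempotent.
#'
#' @param D descriptor matrix.
#' @param var_min variance threshold (default 0.001).
#' @param r2_max squared-correlation threshold (default 0.85).
#' @return The filtered matrix; attribute `removed` is a data.frame
#'   reporting each dropped column and why.
#' @export
pretreat <- function(D, var_min = 0.001, r2_max = 0.85) {
  if (ncol(D) < 2) mtq_stop("mtqsar_pretreat_error", "need >= 2 columns")
  v <- apply(D, 2, var)
  removed <- data.frame(column = character(), reason = character(),
                        stringsAsFactors = FALSE)
  low <- v < var_min
  if (any(low)) {
    removed <- rbind(removed, data.frame(
      column = colnames(D)[low], reason = "low_variance",
      stringsAsFactors = FALSE))
  }
  keep <- which(!low)
  if (length(keep) == 0) {
    mtq_stop("mtqsar_pretreat_error", "all columns removed by pre-treatment")
  }
  R <- suppressWarnings(cor(D[, keep, drop = FALSE]))
  R[is.na(R)] <- 0
  alive <- rep(TRUE, length(keep))
  for (a in seq_along(keep)) {
    if (!alive[a]) next
    for (b in seq_along(keep)) {
      if (b <= a || !alive[b]) next
      if (R[a, b]^2 > r2_max) {
        alive[b] <- FALSE
        removed <- rbind(removed, data.frame(
          column = colnames(D)[keep[b]],
          reason = sprintf("r2=%.3f with %s", R[a, b]^2,
                           colnames(D)[keep[a]]),
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- D[, keep[alive], drop = FALSE]
  if (ncol(out) == 0) {
    mtq_stop("mtqsar_pretreat_error", "all columns removed by pre-treatment")
  }
  for (at in c("config", "table_version")) {
    attr(out, at) <- attr(D, at)
  }
  attr(out, "removed") <- removed
  out
}
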