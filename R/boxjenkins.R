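#' Experimental conditions and Box-Jenkins deviation descriptors
#'
#' Each assay record carries an experimental condition, an ontology
#' cj -> (bt, me) combining the biological target (`bt`, e.g. ERK-1 vs
#' ERK-2) and the measure of effectiveness (`me`, e.g. IC50 vs Ki). The
#' Box-Jenkins moving-average approach replaces every raw descriptor Di by
#' its deviation from the mean of the ACTIVE training compounds that share
#' an experimental element value, producing one deviation column per
#' element (bt and me) per raw descriptor.
#'
#' @name box-jenkins
NULL

CONDITION_ELEMENTS <- c("bt", "me")

#' Default experimental condition set
#'
#' The four combinations of two targets and two effectiveness measures.
#'
#' @param bt_levels,me_levels element value vectors.
#' @return data.frame with columns `condition`, `bt`, `me`.
#' @export
default_conditions <- function(bt_levels = c("ERK-1", "ERK-2"),
                               me_levels = c("IC50", "Ki")) {
  grid <- expand.grid(me = me_levels, bt = bt_levels,
                      stringsAsFactors = FALSE)[, c("bt", "me")]
  data.frame(condition = paste0("c", seq_len(nrow(grid))), grid,
             stringsAsFactors = FALSE)
}

#' Activity labelling at the 500 nM cut-off
#'
#' @param activity_nM positive activity values (IC50 or Ki, nM).
#' @param cutoff_nM cut-off, default 500 nM; the boundary is active
#'   (`<=`).
#' @return Integer vector of class labels, +1 (active) or -1 (inactive).
#' @export
label_activity <- function(activity_nM, cutoff_nM = 500) {
  if (any(is.na(activity_nM)) || any(activity_nM <= 0)) {
    mtq_stop("mtqsar_label_error",
             "activity must be present and positive (nM)")
  }
  ifelse(activity_nM <= cutoff_nM, 1L, -1L)
}

check_records <- function(records, need_label = TRUE) {
  need <- c(CONDITION_ELEMENTS, if (need_label) "label")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    mtq_stop("mtqsar_record_error",
             paste("records lack column(s):", paste(miss, collapse = ", ")))
  }
  invisible(records)
}

#' Per-descriptor means over active training records per element value
#'
#' @param D descriptor matrix, one row per record (aligned with
#'   `records`).
#' @param records data.frame with columns `bt`, `me`, `label`.
#' @param element `"bt"` or `"me"`.
#' @return A `condition_averages` object: per element value, the mean of
#'   every descriptor over active records only, plus active counts.
#' @export
build_condition_averages <- function(D, records, element = c("bt", "me")) {
  element <- match.arg(element)
  check_records(records)
  if (nrow(D) != nrow(records)) {
    mtq_stop("mtqsar_record_error", "descriptor rows != record rows")
  }
  vals <- unique(as.character(records[[element]]))
  means <- matrix(NA_real_, length(vals), ncol(D),
                  dimnames = list(vals, colnames(D)))
  counts <- setNames(integer(length(vals)), vals)
  for (v in vals) {
    sel <- records[[element]] == v & records$label == 1L
    if (!any(sel)) {
      mtq_stop("mtqsar_record_error", sprintf(
        "no active training records for %s = '%s'", element, v))
    }
    means[v, ] <- colMeans(D[sel, , drop = FALSE])
    counts[v] <- sum(sel)
  }
  structure(list(element = element, means = means, counts = counts),
            class = "condition_averages")
}

#' Build averages for both condition elements at once
#'
#' @inheritParams build_condition_averages
#' @return Named list with `bt` and `me` `condition_averages`.
#' @export
build_all_condition_averages <- function(D, records) {
  list(bt = build_condition_averages(D, records, "bt"),
       me = build_condition_averages(D, records, "me"))
}

#' Box-Jenkins deviation descriptors
#'
#' For each record r and element e, `Delta(Di)_e(r) = Di(r) - mean(Di |
#' active training, element value of r)`. Column count doubles: one
#' `D[<name>]bt` and one `D[<name>]me` column per raw descriptor. Element
#' values unseen at training time are a hard error (no silent zero).
#'
#' @param D raw descriptor matrix for the records to transform.
#' @param averages list with `bt` and `me` [build_condition_averages()]
#'   results frozen on the training partition.
#' @param records data.frame with `bt` and `me` columns aligned with `D`.
#' @return Deviation descriptor matrix (rows as `D`, doubled columns).
#' @export
deviation_descriptors <- function(D, averages, records) {
  check_records(records, need_label = FALSE)
  if (nrow(D) != nrow(records)) {
    mtq_stop("mtqsar_record_error", "descriptor rows != record rows")
  }
  blocks <- list()
  for (element in CONDITION_ELEMENTS) {
    avg <- averages[[element]]
    if (is.null(avg) || !inherits(avg, "condition_averages")) {
      mtq_stop("mtqsar_record_error",
               sprintf("missing condition averages for element '%s'", element))
    }
    vals <- as.character(records[[element]])
    unseen <- setdiff(unique(vals), rownames(avg$means))
    if (length(unseen) > 0) {
      mtq_stop("mtqsar_unseen_condition", sprintf(
        "element value(s) never seen at training: %s = %s", element,
        paste(unseen, collapse = ", ")))
    }
    cols <- intersect(colnames(D), colnames(avg$means))
    if (length(cols) != ncol(D)) {
      mtq_stop("mtqsar_record_error",
               "descriptor columns do not match the frozen averages")
    }
    Delta <- D - avg$means[vals, colnames(D), drop = FALSE]
    colnames(Delta) <- paste0("D[", colnames(D), "]", element)
    blocks[[element]] <- Delta
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(D)
  out
}

#' Serialise condition averages to JSON
#'
#' @param averages list with `bt` and `me` `condition_averages`.
#' @param path JSON path.
#' @return `path` invisibly; `read_condition_averages` returns the list.
#' @export
write_condition_averages <- function(averages, path) {
  enc <- lapply(averages, function(a) list(
    element = a$element,
    values = rownames(a$means),
    descriptors = colnames(a$means),
    means = unname(apply(a$means, 1, as.list)),
    counts = as.list(a$counts)))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_condition_averages
#' @export
read_condition_averages <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(enc, function(a) {
    m <- if (is.data.frame(a$means)) as.matrix(a$means) else
      do.call(rbind, lapply(a$means, unlist))
    rownames(m) <- a$values
    colnames(m) <- a$descriptors
    structure(list(element = a$element, means = m,
                   counts = unlist(a$counts)),
              class = "condition_averages")
  })
  names(out) <- vapply(out, function(a) a$element, character(1))
  out
}
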