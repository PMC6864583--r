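#' Configuration for atom-based quadratic indices
#'
#' Total quadratic indices are quadratic forms x' M^k x of an atomic
#' property vector x over powers of a graph matrix: the 0/1 adjacency
#' ("non-stochastic", `ns`) or its row-normalised counterpart
#' ("stochastic", `ss`). Per-atom local indices are aggregated into
#' molecular totals by six operators: Manhattan sum (N1), Euclidean-style
#' sum of squares (N2), geometric mean (GM), range (RA), maximum (MX) and
#' minimum (MN).
#'
#' `k_semantics` selects what "order k" means: `walk_power` (default) uses
#' the k-th matrix power, i.e. counts of length-k walks; alternatively
#' `shortest_path_distance` uses the indicator matrix of topological
#' distance exactly k, matching the "number of bonds between two atoms"
#' reading. The two disagree for k >= 2; both are supported and tested.
#'
#' @param k_max highest order (default 15; orders 0..k_max are computed).
#' @param kinds subset of `c("ns", "ss")`.
#' @param properties subset of the eight atomic properties.
#' @param aggregations subset of `c("N1","N2","GM","RA","MX","MN")`.
#' @param n2_mode `"sum_of_squares"` (default) or `"euclidean_norm"`.
#' @param k_semantics `"walk_power"` or `"shortest_path_distance"`.
#' @return A `quadratic_config` list.
#' @export
quadratic_config <- function(k_max = 15L,
                             kinds = c("ns", "ss"),
                             properties = PROPERTY_NAMES,
                             aggregations = c("N1", "N2", "GM", "RA", "MX", "MN"),
                             n2_mode = c("sum_of_squares", "euclidean_norm"),
                             k_semantics = c("walk_power",
                                             "shortest_path_distance")) {
  n2_mode <- match.arg(n2_mode)
  k_semantics <- match.arg(k_semantics)
  kinds <- match.arg(kinds, c("ns", "ss"), several.ok = TRUE)
  aggregations <- match.arg(aggregations,
                            c("N1", "N2", "GM", "RA", "MX", "MN"),
                            several.ok = TRUE)
  stopifnot(all(properties %in% PROPERTY_NAMES),
            length(properties) > 0, k_max >= 1)
  structure(list(k_max = as.integer(k_max), kinds = kinds,
                 properties = properties, aggregations = aggregations,
                 n2_mode = n2_mode, k_semantics = k_semantics),
            class = "quadratic_config")
}

# Property name token used inside descriptor names (charge prints as CH).
property_token <- function(prop) ifelse(prop == "CHR", "CH", prop)

#' Canonical descriptor column name
#'
#' e.g. `descriptor_name("ns", 13, "VDW", "N2")` is `"Tnsq13(VDW)N2"`: the
#' total non-stochastic quadratic index of order 13 weighted by van der
#' Waals volume, aggregated by sum of squares.
#'
#' @param kind `"ns"` or `"ss"`.
#' @param k order.
#' @param prop property name (charge `CHR` prints as `CH`).
#' @param agg aggregation operator.
#' @return Character name.
#' @export
descriptor_name <- function(kind, k, prop, agg) {
  paste0("T", ifelse(kind == "ns", "nsq", "ssq"), k,
         "(", property_token(prop), ")", agg)
}

#' Graph structure matrix of a given kind and order
#'
#' @param g a `mol_graph`.
#' @param kind `"ns"` (0/1 adjacency) or `"ss"` (row-stochastic adjacency).
#' @param k non-negative order; `k = 0` gives the identity.
#' @param k_semantics see [quadratic_config()].
#' @return Square numeric matrix.
#' @export
structure_matrix <- function(g, kind = c("ns", "ss"), k,
                             k_semantics = c("walk_power",
                                             "shortest_path_distance")) {
  kind <- match.arg(kind)
  k_semantics <- match.arg(k_semantics)
  if (k < 0) mtq_stop("mtqsar_descriptor_error", "negative order k")
  n <- n_atoms(g)
  if (n == 1) return(matrix(1, 1, 1))
  A <- adjacency_matrix(g)
  if (k_semantics == "walk_power") {
    M <- A
    if (kind == "ss") M <- row_normalise(A)
    out <- diag(n)
    if (k > 0) for (t in seq_len(k)) out <- out %*% M
    return(out)
  }
  ig <- as_igraph(g)
  Dm <- igraph::distances(ig)
  ind <- (Dm == k) * 1
  dimnames(ind) <- NULL
  if (kind == "ss") ind <- row_normalise(ind)
  ind
}

row_normalise <- function(A) {
  rs <- rowSums(A)
  nz <- rs > 0
  A[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
  A
}

#' Local quadratic index vector
#'
#' Per-atom values `Lq_k(x, i) = sum_j [M^k]_ij x_i x_j`.
#'
#' @param g a `mol_graph`.
#' @param kind,k,k_semantics as in [structure_matrix()].
#' @param x numeric atomic property vector (length = heavy atoms).
#' @return Numeric vector of per-atom local indices.
#' @export
local_quadratic_index <- function(g, kind, k, x,
                                  k_semantics = "walk_power") {
  if (length(x) != n_atoms(g)) {
    mtq_stop("mtqsar_descriptor_error",
             "property vector length does not match atom count")
  }
  M <- structure_matrix(g, kind, k, k_semantics)
  as.numeric(x * (M %*% x))
}

#' Aggregate local indices into a total index
#'
#' N1 = sum; N2 = sum of squares (as printed; `euclidean_norm` takes the
#' square root); GM = sign-preserving n-th root of the product (0 when any
#' local value is 0); RA = max - min; MX = max; MN = min.
#'
#' @param locals numeric vector of local indices.
#' @param agg one of `"N1","N2","GM","RA","MX","MN"`.
#' @param n2_mode see [quadratic_config()].
#' @return Scalar total index (never NaN).
#' @export
total_index <- function(locals, agg = c("N1", "N2", "GM", "RA", "MX", "MN"),
                        n2_mode = "sum_of_squares") {
  agg <- match.arg(agg)
  if (length(locals) == 0) {
    mtq_stop("mtqsar_descriptor_error", "empty local index vector")
  }
  switch(agg,
    N1 = sum(locals),
    N2 = if (n2_mode == "euclidean_norm") sqrt(sum(locals^2)) else
      sum(locals^2),
    GM = {
      if (any(locals == 0)) 0 else {
        lp <- sum(log(abs(locals)))
        s <- if (sum(locals < 0) %% 2 == 1) -1 else 1
        s * exp(lp / length(locals))
      }
    },
    RA = max(locals) - min(locals),
    MX = max(locals),
    MN = min(locals))
}

# All totals for one molecule under a config, as a named numeric vector.
molecule_descriptors <- function(g, cfg, props = NULL,
                                 tables = load_property_tables()) {
  if (is.null(props)) {
    props <- assign_properties(g, tables, properties = cfg$properties)
  }
  n <- n_atoms(g)
  X <- props[, cfg$properties, drop = FALSE]
  n_cols <- length(cfg$kinds) * (cfg$k_max + 1) * ncol(X) *
    length(cfg$aggregations)
  vals <- numeric(n_cols)
  nms <- character(n_cols)
  pos <- 0L
  A <- adjacency_matrix(g)
  ig_dist <- NULL
  if (cfg$k_semantics == "shortest_path_distance" && n > 1) {
    ig_dist <- igraph::distances(as_igraph(g))
  }
  for (kind in cfg$kinds) {
    if (cfg$k_semantics == "walk_power") {
      M <- if (kind == "ss" && n > 1) row_normalise(A) else A
      P <- diag(n)
    }
    for (k in 0:cfg$k_max) {
      if (cfg$k_semantics == "walk_power") {
        if (k > 0) P <- P %*% M
        Pk <- P
      } else {
        if (n == 1) {
          Pk <- matrix(as.numeric(k == 0), 1, 1)
        } else {
          Pk <- (ig_dist == k) * 1
          if (kind == "ss") Pk <- row_normalise(Pk)
        }
      }
      L <- X * (Pk %*% X)   # columns: local index vectors per property
      # vectorised totals: one row per aggregation, one column per property
      stat <- matrix(NA_real_, length(cfg$aggregations), ncol(L))
      mx <- apply(L, 2, max); mn <- apply(L, 2, min)
      for (ai in seq_along(cfg$aggregations)) {
        stat[ai, ] <- switch(cfg$aggregations[ai],
          N1 = colSums(L),
          N2 = if (cfg$n2_mode == "euclidean_norm") sqrt(colSums(L^2)) else
            colSums(L^2),
          GM = apply(L, 2, total_index, agg = "GM"),
          RA = mx - mn, MX = mx, MN = mn)
      }
      span <- length(cfg$aggregations) * ncol(L)
      vals[pos + seq_len(span)] <- as.vector(stat)
      nms[pos + seq_len(span)] <- as.vector(vapply(
        cfg$properties, function(p) descriptor_name(kind, k, p,
                                                    cfg$aggregations),
        character(length(cfg$aggregations))))
      pos <- pos + span
    }
  }
  names(vals) <- nms
  if (any(!is.finite(vals))) {
    mtq_stop("mtqsar_descriptor_error",
             sprintf("non-finite descriptor for '%s'", g$id))
  }
  vals
}

#' Compute the descriptor matrix for a dataset of molecules
#'
#' @param graphs list of `mol_graph`.
#' @param cfg a [quadratic_config()].
#' @param tables property table set.
#' @param strict abort on any per-molecule failure (default); otherwise
#'   drop the molecule with a warning.
#' @return Numeric matrix (molecules x descriptors) with compound ids as
#'   row names and canonical descriptor names as column names; attributes
#'   `config` and `table_version` record provenance.
#' @export
compute_descriptor_matrix <- function(graphs, cfg = quadratic_config(),
                                      tables = load_property_tables(),
                                      strict = TRUE) {
  rows <- vector("list", length(graphs))
  ok <- rep(TRUE, length(graphs))
  for (m in seq_along(graphs)) {
    r <- tryCatch(molecule_descriptors(graphs[[m]], cfg, tables = tables),
                  error = function(e) e)
    if (inherits(r, "error")) {
      msg <- sprintf("molecule '%s': %s", graphs[[m]]$id, conditionMessage(r))
      if (strict) mtq_stop("mtqsar_descriptor_error", msg)
      warning(msg, call. = FALSE)
      ok[m] <- FALSE
    } else rows[[m]] <- r
  }
  rows <- rows[ok]
  if (length(rows) == 0) {
    mtq_stop("mtqsar_descriptor_error", "no molecules could be processed")
  }
  D <- do.call(rbind, rows)
  rownames(D) <- vapply(graphs[ok], function(g) g$id, character(1))
  attr(D, "config") <- cfg
  attr(D, "table_version") <- tables$manifest$version %||% "unversioned"
  D
}

#' Write / read a descriptor matrix as CSV with a JSON sidecar
#'
#' The sidecar records the descriptor configuration and property-table
#' version so matrices are reproducible artefacts.
#'
#' @param D descriptor matrix from [compute_descriptor_matrix()].
#' @param path CSV path (`<path>.json` is written next to it).
#' @return `path`, invisibly (`read_descriptor_matrix` returns the matrix).
#' @export
write_descriptor_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  cfg <- attr(D, "config")
  jsonlite::write_json(
    list(config = unclass(cfg),
         table_version = attr(D, "table_version") %||% "unversioned",
         n_compounds = nrow(D), n_descriptors = ncol(D)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df[[1]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- meta$config
    attr(D, "config") <- do.call(quadratic_config, cfg[c(
      "k_max", "kinds", "properties", "aggregations", "n2_mode",
      "k_semantics")])
    attr(D, "table_version") <- meta$table_version
  }
  D
}
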