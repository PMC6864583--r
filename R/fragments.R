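#' Ring perception, Bemis-Murcko scaffolds and fragment scoring
#'
#' Fragment analysis ranks the single-ring systems that recur across a
#' dataset by the contribution the linear discriminant model assigns to
#' them: each frequent ring is scored as a standalone molecule under every
#' experimental condition, the scores are standardised jointly, and the
#' per-fragment mean of the standardised scores across conditions is the
#' average confidence score (ACS).
#'
#' @name fragment-analysis
NULL

# Smallest ring through every non-bridge edge: the union over edges of
# (shortest path between the endpoints avoiding the edge) + the edge.
# For ordinary fused/spiro systems this reproduces the smallest set of
# smallest rings; returns atom index vectors in cyclic order.
smallest_rings <- function(g) {
  if (n_atoms(g) < 3 || nrow(g$bonds) < 3) return(list())
  ig <- as_igraph(g)
  br <- as.integer(igraph::bridges(ig))
  cyc_edges <- setdiff(seq_len(igraph::ecount(ig)), br)
  out <- list(); seen <- character()
  for (e in cyc_edges) {
    ends <- as.integer(igraph::ends(ig, e))
    gm <- igraph::delete_edges(ig, e)
    sp <- suppressWarnings(igraph::shortest_paths(gm, from = ends[1],
                                                  to = ends[2]))
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) < 3) next
    key <- paste(sort(vp), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- vp
  }
  out
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively deletes degree-1 atoms until a fixed point, leaving ring
#' systems plus the linker paths between them. Acyclic molecules give an
#' empty scaffold (`NULL`).
#'
#' @param g a `mol_graph`.
#' @return A `mol_graph` scaffold, or `NULL` for acyclic input.
#' @export
murcko_scaffold <- function(g) {
  keep <- seq_len(n_atoms(g))
  bonds <- g$bonds
  repeat {
    if (length(keep) == 0) return(NULL)
    deg <- tabulate(c(bonds$i, bonds$j), nbins = n_atoms(g))
    leaves <- intersect(keep, which(deg <= 1))
    if (length(leaves) == 0) break
    keep <- setdiff(keep, leaves)
    bonds <- bonds[!(bonds$i %in% leaves | bonds$j %in% leaves), , drop = FALSE]
  }
  if (length(keep) == 0) return(NULL)
  sg <- induced_mol_subgraph(g, keep)
  sg$id <- paste0(g$id, "_scaffold")
  sg
}

# Canonical key of a single ring: lexicographically minimal rotation /
# reflection of the around-the-ring (element, aromatic) sequence.
ring_canonical_key <- function(elements, aromatic) {
  syms <- ifelse(aromatic, tolower(elements), elements)
  m <- length(syms)
  best <- NULL
  for (dir in list(syms, rev(syms))) {
    for (s in seq_len(m)) {
      rot <- c(dir[s:m], if (s > 1) dir[1:(s - 1)])
      cand <- paste(rot, collapse = "-")
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

# SMILES for a single ring treated as a standalone molecule with implicit
# hydrogens. Aromatic five-membered rings that need an explicit pyrrole-type
# [nH] are retried with the substitution.
ring_fragment_smiles <- function(elements, aromatic) {
  syms <- ifelse(rep(all(aromatic), length(elements)),
                 tolower(elements), elements)
  wrap <- function(s) ifelse(nchar(s) > 1 & s == tolower(s),
                             paste0("[", s, "]"), s)
  mk <- function(ss) paste0(wrap(ss[1]), "1",
                            paste(vapply(ss[-1], wrap, character(1)),
                                  collapse = ""), "1")
  smi <- mk(syms)
  g <- tryCatch(parse_smiles(smi), error = function(e) NULL)
  if (is.null(g) && any(syms == "n")) {
    syms2 <- syms
    syms2[which(syms2 == "n")[1]] <- "[nH]"
    smi <- mk(syms2)
    g <- tryCatch(parse_smiles(smi), error = function(e) NULL)
  }
  if (is.null(g)) {
    smi <- mk(toupper(syms))
    g <- tryCatch(parse_smiles(smi), error = function(e) NULL)
  }
  if (is.null(g)) return(NULL)
  g$id <- smi
  g
}

#' Enumerate frequent single-ring fragments in a dataset
#'
#' Scaffolds are extracted per compound, their smallest rings enumerated,
#' and each distinct ring (element sequence + aromaticity, up to rotation
#' and reflection) counted once per compound. Fragments present in more
#' than `min_compounds` compounds are kept (strict inequality).
#'
#' @param graphs list of `mol_graph`.
#' @param min_compounds frequency threshold (default 15, strict `>`).
#' @return data.frame with `fragment` (SMILES), `key`, `n_compounds`, plus
#'   a list-column `graph` of the standalone ring molecules.
#' @export
enumerate_ring_fragments <- function(graphs, min_compounds = 15L) {
  counts <- list()
  for (g in graphs) {
    sc <- murcko_scaffold(g)
    if (is.null(sc)) next
    rings <- smallest_rings(sc)
    if (length(rings) == 0) next
    arom <- aromatic_flags(sc)
    keys_seen <- character()
    for (ring in rings) {
      key <- ring_canonical_key(sc$atoms$element[ring], arom[ring])
      if (key %in% keys_seen) next  # once per compound
      keys_seen <- c(keys_seen, key)
      if (is.null(counts[[key]])) {
        counts[[key]] <- list(n = 0L, elements = sc$atoms$element[ring],
                              aromatic = arom[ring])
      }
      counts[[key]]$n <- counts[[key]]$n + 1L
    }
  }
  if (length(counts) == 0) {
    return(data.frame(fragment = character(), key = character(),
                      n_compounds = integer()))
  }
  keys <- names(counts)
  n_cmp <- vapply(counts, function(x) x$n, integer(1))
  keep <- n_cmp > min_compounds
  keys <- keys[keep]; n_cmp <- n_cmp[keep]
  frag_graphs <- list(); frag_smiles <- character()
  ok <- logical(length(keys))
  for (k in seq_along(keys)) {
    fg <- ring_fragment_smiles(counts[[keys[k]]]$elements,
                               counts[[keys[k]]]$aromatic)
    ok[k] <- !is.null(fg)
    if (ok[k]) {
      frag_graphs[[length(frag_graphs) + 1]] <- fg
      frag_smiles <- c(frag_smiles, fg$id)
    }
  }
  out <- data.frame(fragment = frag_smiles, key = keys[ok],
                    n_compounds = n_cmp[ok], stringsAsFactors = FALSE)
  ord <- order(-out$n_compounds, out$key)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "graphs") <- frag_graphs[ord]
  out
}

#' Raw fragment scores under each experimental condition
#'
#' The model's raw descriptors are computed on each fragment as a
#' standalone molecule, converted to condition-deviation descriptors with
#' the frozen training condition averages for each condition, and pushed
#' through the linear model.
#'
#' @param fragments result of [enumerate_ring_fragments()].
#' @param model a [lda_model()].
#' @param conditions data.frame with columns `condition`, `bt`, `me` (one
#'   row per experimental condition; see [default_conditions()]).
#' @param averages condition averages from [build_condition_averages()]
#'   (list with `bt` and `me` components).
#' @param cfg descriptor configuration used at training time.
#' @return A `fragment_score_table`: matrix fragments x conditions of raw
#'   scores with the fragment table as attribute.
#' @export
fragment_scores <- function(fragments, model, conditions, averages,
                            cfg = quadratic_config()) {
  graphs <- attr(fragments, "graphs")
  if (is.null(graphs) || length(graphs) == 0) {
    mtq_stop("mtqsar_fragment_error", "no fragment graphs to score")
  }
  D <- compute_descriptor_matrix(graphs, cfg)
  # restrict to the descriptor set the frozen averages know about
  # (the training pipeline pre-treats columns before freezing them)
  want <- colnames(averages[[1]]$means)
  miss <- setdiff(want, colnames(D))
  if (length(miss) > 0) {
    mtq_stop("mtqsar_fragment_error", paste(
      "fragment descriptors missing under this config:",
      paste(head(miss, 3), collapse = ", ")))
  }
  D <- D[, want, drop = FALSE]
  raw <- matrix(NA_real_, nrow(fragments), nrow(conditions),
                dimnames = list(fragments$fragment, conditions$condition))
  for (ci in seq_len(nrow(conditions))) {
    recs <- data.frame(bt = rep(conditions$bt[ci], nrow(D)),
                       me = rep(conditions$me[ci], nrow(D)))
    Dd <- deviation_descriptors(D, averages, recs)
    raw[, ci] <- score_linear(model, Dd)
  }
  structure(raw, class = c("fragment_score_table", "matrix"),
            fragments = fragments, standardised = FALSE)
}

#' Standardise fragment scores and compute average confidence scores
#'
#' Raw scores are z-standardised jointly over all fragment-by-condition
#' cells (sample SD, n-1); the ACS of a fragment is the mean of its
#' standardised scores across conditions. Per-condition standardisation is
#' available behind `per_condition = TRUE`.
#'
#' @param raw a `fragment_score_table` of raw scores.
#' @param per_condition standardise within each condition column instead
#'   of over all cells jointly.
#' @return list with `z` (standardised matrix), `acs` (named vector sorted
#'   decreasing) and `table` (data.frame report).
#' @export
standardize_scores <- function(raw, per_condition = FALSE) {
  if (length(raw) < 2) {
    mtq_stop("mtqsar_fragment_error", "need at least 2 score cells")
  }
  if (per_condition) {
    z <- apply(raw, 2, function(col) {
      s <- sd(col)
      if (s == 0) mtq_stop("mtqsar_fragment_error",
                           "zero standard deviation in scores")
      (col - mean(col)) / s
    })
    dimnames(z) <- dimnames(raw)
  } else {
    s <- sd(as.vector(raw))
    if (s == 0) {
      mtq_stop("mtqsar_fragment_error", "zero standard deviation in scores")
    }
    z <- (raw - mean(raw)) / s
  }
  acs <- rowMeans(z)
  ord <- order(-acs)
  tab <- data.frame(fragment = rownames(raw)[ord],
                    as.data.frame(z[ord, , drop = FALSE]),
                    ACS = acs[ord], check.names = FALSE)
  rownames(tab) <- NULL
  list(z = z, acs = sort(acs, decreasing = TRUE), table = tab)
}

#' Write a fragment contribution report
#'
#' @param std result of [standardize_scores()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_fragment_report <- function(std, path) {
  write.csv(std$table, path, row.names = FALSE)
  invisible(path)
}
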