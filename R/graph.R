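#' Molecular graph objects
#'
#' A `mol_graph` is the hydrogen-suppressed molecular graph that underlies
#' every descriptor in the package: an ordered atom table (element symbol,
#' formal charge, attached-hydrogen count) plus an undirected bond list.
#' Bond orders are carried along for property typing (e.g. deciding whether
#' a nitrogen is aromatic when assigning polar-surface-area contributions)
#' but play no role in the graph topology itself: adjacency is 0/1 and
#' topological distances are counted in bonds without regard to
#' multiplicity.
#'
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer formal charge) and `nH` (attached hydrogen count).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices,
#'   `i < j`) and `order` (1, 2 or 3).
#' @param id compound identifier string.
#' @param smiles SMILES string the graph was parsed from, if any.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, id = "", smiles = NA_character_) {
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      nH = as.integer(atoms$nH),
                      stringsAsFactors = FALSE)
  if (nrow(bonds) > 0) {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (any(bonds$i == bonds$j)) {
      mtq_stop("mtqsar_graph_error", "self-loop bond in molecular graph")
    }
    if (any(bonds$j > nrow(atoms)) || any(bonds$i < 1L)) {
      mtq_stop("mtqsar_graph_error", "bond refers to a non-existent atom")
    }
    if (anyDuplicated(bonds[, c("i", "j")])) {
      mtq_stop("mtqsar_graph_error", "duplicate bond in molecular graph")
    }
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  structure(list(atoms = atoms, bonds = bonds, id = id, smiles = smiles),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d heavy atoms, %d bonds%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (!is.na(x$smiles)) paste0(", ", x$smiles) else ""))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Hydrogen-suppressed 0/1 adjacency matrix
#'
#' Bond multiplicity is deliberately ignored: a double or aromatic bond
#' contributes the same single edge as a single bond.
#'
#' @param g a `mol_graph`.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(g) {
  n <- n_atoms(g)
  A <- matrix(0, n, n)
  if (nrow(g$bonds) > 0) {
    A[cbind(g$bonds$i, g$bonds$j)] <- 1
    A[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  A
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds) > 0) g$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# TRUE for each atom that lies on at least one cycle (incident to a
# non-bridge edge).
ring_atom_flags <- function(g) {
  n <- n_atoms(g)
  if (n == 0 || nrow(g$bonds) == 0) return(rep(FALSE, n))
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  flags <- rep(FALSE, n)
  if (igraph::ecount(ig) > length(br)) {
    keep <- setdiff(seq_len(igraph::ecount(ig)), as.integer(br))
    for (e in keep) {
      ends <- igraph::ends(ig, e)
      flags[as.integer(ends)] <- TRUE
    }
  }
  flags
}

# Highest bond order incident to each atom (1 for isolated atoms).
max_bond_order <- function(g) {
  n <- n_atoms(g)
  mb <- rep(1L, n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[r]
      mb[g$bonds$i[r]] <- max(mb[g$bonds$i[r]], o)
      mb[g$bonds$j[r]] <- max(mb[g$bonds$j[r]], o)
    }
  }
  mb
}

# Aromatic-like flag per atom: the atom sits on a ring at least half of
# whose bonds are double bonds (a kekulised aromatic ring alternates
# single/double). This is a typing heuristic used only for property
# assignment, never for topology.
aromatic_flags <- function(g) {
  n <- n_atoms(g)
  flags <- rep(FALSE, n)
  rings <- smallest_rings(g)
  if (length(rings) == 0) return(flags)
  bond_key <- paste(g$bonds$i, g$bonds$j)
  for (ring in rings) {
    m <- length(ring)
    nxt <- c(ring[-1], ring[1])
    lo <- pmin(ring, nxt); hi <- pmax(ring, nxt)
    idx <- match(paste(lo, hi), bond_key)
    orders <- g$bonds$order[idx]
    # a kekulised aromatic ring has floor(m/2) double bonds
    if (sum(orders >= 2, na.rm = TRUE) >= floor(m / 2)) flags[ring] <- TRUE
  }
  flags
}

#' Parse SMILES strings into molecular graphs
#'
#' Chemistry (grammar, kekulisation, implicit hydrogens) is delegated to
#' OpenBabel; the resulting connection table is converted to a
#' hydrogen-suppressed [mol_graph()] with per-atom attached-H counts.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers (default `mol1`, `mol2`, ...).
#' @param keep_largest_fragment multi-fragment (dot-separated) input is an
#'   error unless this is `TRUE`, in which case only the largest connected
#'   heavy-atom fragment is retained (salt stripping).
#' @return For a single SMILES, a `mol_graph`; for a vector, a list of them.
#' @export
parse_smiles <- function(smiles, ids = NULL, keep_largest_fragment = FALSE) {
  single <- length(smiles) == 1L
  res <- parse_smiles_batch(smiles, ids = ids,
                            keep_largest_fragment = keep_largest_fragment,
                            strict = TRUE)
  if (single) res$graphs[[1]] else res$graphs
}

# Cheap syntactic pre-check so parse failures report a token position.
smiles_precheck <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list(position = 0L, message = "empty SMILES"))
  chars <- strsplit(s, "")[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9),
               "(", ")", "[", "]", "=", "#", "+", "-", "%", "/", "\\",
               ".", "@", ":", "*")
  ok <- chars %in% allowed
  if (any(!ok)) {
    p <- which(!ok)[1]
    return(list(position = p,
                message = sprintf("invalid character '%s'", chars[p])))
  }
  depth_p <- 0L; depth_b <- 0L
  ring_open <- integer()
  i <- 1L
  in_bracket <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      if (in_bracket) return(list(position = i, message = "nested '['"))
      in_bracket <- TRUE; depth_b <- depth_b + 1L
    } else if (ch == "]") {
      if (!in_bracket) return(list(position = i, message = "unmatched ']'"))
      in_bracket <- FALSE; depth_b <- depth_b - 1L
    } else if (!in_bracket) {
      if (ch == "(") depth_p <- depth_p + 1L
      if (ch == ")") {
        depth_p <- depth_p - 1L
        if (depth_p < 0L) return(list(position = i, message = "unmatched ')'"))
      }
      if (grepl("[0-9]", ch)) {
        d <- as.integer(ch)
        if (d %in% ring_open) ring_open <- setdiff(ring_open, d)
        else ring_open <- c(ring_open, d)
      }
      if (ch == "%") {
        if (i + 2L > length(chars) ||
            !grepl("[0-9]", chars[i + 1]) || !grepl("[0-9]", chars[i + 2])) {
          return(list(position = i, message = "malformed '%' ring bond"))
        }
        d <- as.integer(paste0(chars[i + 1], chars[i + 2]))
        if (d %in% ring_open) ring_open <- setdiff(ring_open, d)
        else ring_open <- c(ring_open, d)
        i <- i + 2L
      }
    }
    i <- i + 1L
  }
  if (in_bracket) return(list(position = length(chars), message = "unclosed '['"))
  if (depth_p > 0L) return(list(position = length(chars), message = "unclosed '('"))
  if (length(ring_open) > 0L) {
    return(list(position = length(chars),
                message = sprintf("unmatched ring bond %d", ring_open[1])))
  }
  NULL
}

# Batch SMILES -> graphs via one obabel call. Returns list(graphs, failed).
parse_smiles_batch <- function(smiles, ids = NULL,
                               keep_largest_fragment = FALSE,
                               strict = TRUE) {
  n <- length(smiles)
  if (n == 0) return(list(graphs = list(), failed = integer()))
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  failed <- integer()
  fail_msg <- character()
  usable <- rep(TRUE, n)
  for (k in seq_len(n)) {
    pc <- smiles_precheck(smiles[k])
    if (!is.null(pc)) {
      usable[k] <- FALSE
      failed <- c(failed, k)
      fail_msg <- c(fail_msg, sprintf("record %d ('%s') at position %d: %s",
                                      k, ids[k], pc$position, pc$message))
      next
    }
    if (grepl(".", smiles[k], fixed = TRUE) && !keep_largest_fragment) {
      usable[k] <- FALSE
      failed <- c(failed, k)
      fail_msg <- c(fail_msg, sprintf(
        "record %d ('%s'): multi-fragment SMILES (use keep_largest_fragment = TRUE)",
        k, ids[k]))
    }
  }
  if (strict && length(failed) > 0) {
    mtq_stop("mtqsar_parse_error", paste(fail_msg, collapse = "; "))
  }
  graphs <- vector("list", n)
  idx <- which(usable)
  if (length(idx) > 0) {
    tmp_in <- tempfile(fileext = ".smi")
    tmp_out <- tempfile(fileext = ".sdf")
    on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
    writeLines(paste(smiles[idx], seq_along(idx)), tmp_in)
    run_obabel(c(tmp_in, "-osdf", "-h", "-O", tmp_out))
    sdf_lines <- if (file.exists(tmp_out)) readLines(tmp_out) else character()
    recs <- split_sdf_records(sdf_lines)
    got <- rep(FALSE, length(idx))
    for (rec in recs) {
      pos <- suppressWarnings(as.integer(trimws(rec[1])))
      if (is.na(pos) || pos < 1 || pos > length(idx)) next
      k <- idx[pos]
      gr <- tryCatch(v2000_to_graph(rec, id = ids[k], smiles = smiles[k]),
                     error = function(e) NULL)
      if (is.null(gr)) next
      if (keep_largest_fragment) gr <- largest_fragment(gr)
      graphs[[k]] <- gr
      got[pos] <- TRUE
    }
    miss <- idx[!got]
    if (length(miss) > 0) {
      msgs <- sprintf("record %d ('%s'): OpenBabel could not parse '%s'",
                      miss, ids[miss], smiles[miss])
      if (strict) mtq_stop("mtqsar_parse_error", paste(msgs, collapse = "; "))
      failed <- c(failed, miss)
      fail_msg <- c(fail_msg, msgs)
    }
  }
  if (length(failed) > 0 && !strict) {
    warning(sprintf("%d record(s) skipped: %s", length(failed),
                    paste(fail_msg, collapse = "; ")), call. = FALSE)
  }
  list(graphs = graphs[!vapply(graphs, is.null, logical(1))],
       failed = sort(failed), messages = fail_msg)
}

split_sdf_records <- function(lines) {
  if (length(lines) == 0) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) return(list(lines))
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

# Extract a mol_graph from one V2000 record (explicit hydrogens expected,
# which are folded into per-heavy-atom nH counts).
v2000_to_graph <- function(rec, id = "", smiles = NA_character_) {
  if (length(rec) < 4) mtq_stop("mtqsar_parse_error", "truncated SDF record")
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) mtq_stop("mtqsar_parse_error", "bad counts line")
  atom_lines <- rec[5:(4 + na)]
  element <- trimws(substr(atom_lines, 32, 34))
  ccode <- suppressWarnings(as.integer(trimws(substr(atom_lines, 37, 39))))
  ccode[is.na(ccode)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[ccode + 1L]
  bi <- integer(nb); bj <- integer(nb); bo <- integer(nb)
  if (nb > 0) {
    bond_lines <- rec[(5 + na):(4 + na + nb)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
    bo[bo == 4L] <- 1L  # aromatic bond code: topology only
  }
  # M  CHG lines override the legacy charge column
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  for (cl in chg_lines) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    cnt <- as.integer(toks[3])
    for (p in seq_len(cnt)) {
      a <- as.integer(toks[2 + 2 * p])
      v <- as.integer(toks[3 + 2 * p])
      charge[a] <- v
    }
  }
  is_h <- element == "H"
  if (all(is_h)) mtq_stop("mtqsar_parse_error", "no heavy atoms")
  heavy_idx <- which(!is_h)
  remap <- integer(length(element)); remap[heavy_idx] <- seq_along(heavy_idx)
  nH <- integer(length(heavy_idx))
  keep_i <- integer(); keep_j <- integer(); keep_o <- integer()
  for (r in seq_len(nb)) {
    a <- bi[r]; b <- bj[r]
    if (is_h[a] && is_h[b]) next
    if (is_h[a]) { nH[remap[b]] <- nH[remap[b]] + 1L; next }
    if (is_h[b]) { nH[remap[a]] <- nH[remap[a]] + 1L; next }
    keep_i <- c(keep_i, remap[a]); keep_j <- c(keep_j, remap[b])
    keep_o <- c(keep_o, bo[r])
  }
  mol_graph(
    atoms = data.frame(element = element[heavy_idx],
                       charge = charge[heavy_idx], nH = nH),
    bonds = data.frame(i = keep_i, j = keep_j, order = keep_o),
    id = id, smiles = smiles)
}

# Keep the largest connected heavy-atom component (salt stripping).
largest_fragment <- function(g) {
  if (n_atoms(g) <= 1 || nrow(g$bonds) == 0) {
    if (n_atoms(g) > 1 && nrow(g$bonds) == 0) {
      return(induced_mol_subgraph(g, 1L))
    }
    return(g)
  }
  comp <- igraph::components(as_igraph(g))
  if (comp$no == 1) return(g)
  big <- which.max(comp$csize)
  induced_mol_subgraph(g, which(comp$membership == big))
}

# Induced subgraph on a set of atom indices, re-indexed densely.
induced_mol_subgraph <- function(g, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- integer(n_atoms(g)); remap[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, , drop = FALSE]
  mol_graph(atoms = g$atoms[keep, , drop = FALSE],
            bonds = data.frame(i = remap[b$i], j = remap[b$j], order = b$order),
            id = g$id, smiles = NA_character_)
}

# Serialise a mol_graph as a V2000 block with explicit hydrogens so that
# OpenBabel can regenerate a SMILES without guessing hydrogen counts.
graph_to_sdf_text <- function(g) {
  nh_tot <- sum(g$atoms$nH)
  na <- n_atoms(g) + nh_tot
  h_i <- integer(); h_j <- integer()
  hpos <- n_atoms(g)
  for (a in seq_len(n_atoms(g))) {
    if (g$atoms$nH[a] > 0) {
      for (q in seq_len(g$atoms$nH[a])) {
        hpos <- hpos + 1L
        h_i <- c(h_i, a); h_j <- c(h_j, hpos)
      }
    }
  }
  nb <- nrow(g$bonds) + length(h_i)
  lines <- c(g$id, " mtqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  elems <- c(g$atoms$element, rep("H", nh_tot))
  for (a in seq_len(na)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, elems[a]))
  }
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                g$bonds$i[r], g$bonds$j[r], g$bonds$order[r]))
    }
  }
  if (length(h_i) > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", h_i, h_j, 1L))
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg) > 0) {
    for (a in chg) {
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", a, g$atoms$charge[a]))
    }
  }
  c(lines, "M  END", "$$$$")
}

#' Write a molecular graph back to SMILES
#'
#' @param g a `mol_graph`.
#' @param canonical regenerate a canonical SMILES via OpenBabel even when
#'   the graph still carries the SMILES it was parsed from.
#' @return SMILES string.
#' @export
write_smiles <- function(g, canonical = FALSE) {
  if (!canonical && !is.na(g$smiles)) return(g$smiles)
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".smi")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(graph_to_sdf_text(g), tmp_in)
  run_obabel(c(tmp_in, "-ocan", "-O", tmp_out))
  out <- if (file.exists(tmp_out)) readLines(tmp_out) else character()
  if (length(out) == 0) {
    mtq_stop("mtqsar_parse_error",
             sprintf("could not generate SMILES for '%s'", g$id))
  }
  strsplit(trimws(out[1]), "\\s+")[[1]][1]
}

# Canonical structure key used for deduplication.
canonical_smiles <- function(g) write_smiles(g, canonical = TRUE)

#' Read a table of structures with annotations
#'
#' Supported formats: `.smi` (one record per line, optional identifier
#' after whitespace), SDF (V2000; data fields become annotations) and CSV
#' with a declared SMILES column.
#'
#' @param path file path.
#' @param format one of `"smi"`, `"sdf"`, `"csv"` (default guessed from the
#'   file extension).
#' @param smiles_col,id_col CSV column names holding the SMILES and the
#'   compound identifier.
#' @param strict abort on the first unparseable record instead of logging
#'   and skipping it.
#' @param keep_largest_fragment passed to the SMILES parser.
#' @return list with `graphs` (list of `mol_graph`) and `annotations`
#'   (data.frame, one row per parsed record).
#' @export
read_structure_table <- function(path, format = c("auto", "smi", "sdf", "csv"),
                                 smiles_col = "smiles", id_col = "id",
                                 strict = FALSE,
                                 keep_largest_fragment = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    mtq_stop("mtqsar_io_error", sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", mol = "sdf",
                     csv = "csv",
                     mtq_stop("mtqsar_io_error",
                              sprintf("cannot guess format of '%s'", path)))
  }
  if (format == "sdf") return(read_sdf_table(path, strict = strict))
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("empty structure file: ", path, call. = FALSE)
      return(list(graphs = list(), annotations = data.frame()))
    }
    toks <- strsplit(trimws(lines), "\\s+")
    smiles <- vapply(toks, `[[`, character(1), 1)
    ids <- vapply(seq_along(toks), function(k) {
      if (length(toks[[k]]) > 1) toks[[k]][2] else paste0("mol", k)
    }, character(1))
    ann <- data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0) {
      warning("empty structure file: ", path, call. = FALSE)
      return(list(graphs = list(), annotations = data.frame()))
    }
    if (!smiles_col %in% names(tab)) {
      mtq_stop("mtqsar_io_error",
               sprintf("CSV lacks declared SMILES column '%s'", smiles_col))
    }
    smiles <- as.character(tab[[smiles_col]])
    ids <- if (id_col %in% names(tab)) as.character(tab[[id_col]]) else
      paste0("mol", seq_len(nrow(tab)))
    ann <- tab
    if (!id_col %in% names(ann)) ann[[id_col]] <- ids
  }
  res <- parse_smiles_batch(smiles, ids = ids,
                            keep_largest_fragment = keep_largest_fragment,
                            strict = strict)
  keep <- setdiff(seq_along(smiles), res$failed)
  message(sprintf("read_structure_table: %d of %d record(s) parsed from %s",
                  length(keep), length(smiles), path))
  list(graphs = res$graphs, annotations = ann[keep, , drop = FALSE])
}

read_sdf_table <- function(path, strict = FALSE) {
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp_out), add = TRUE)
  run_obabel(c("-isdf", path, "-osdf", "-h", "-O", tmp_out))
  lines <- if (file.exists(tmp_out)) readLines(tmp_out) else character()
  recs <- split_sdf_records(lines)
  if (length(recs) == 0) {
    warning("empty structure file: ", path, call. = FALSE)
    return(list(graphs = list(), annotations = data.frame()))
  }
  graphs <- list(); anns <- list()
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    id <- trimws(rec[1]); if (!nzchar(id)) id <- paste0("mol", k)
    gr <- tryCatch(v2000_to_graph(rec, id = id), error = function(e) e)
    if (inherits(gr, "error")) {
      msg <- sprintf("SDF record %d ('%s'): %s", k, id, conditionMessage(gr))
      if (strict) mtq_stop("mtqsar_parse_error", msg)
      warning(msg, call. = FALSE)
      next
    }
    ann <- sdf_data_fields(rec)
    ann$id <- id
    graphs[[length(graphs) + 1]] <- gr
    anns[[length(anns) + 1]] <- ann
  }
  fields <- unique(unlist(lapply(anns, names)))
  ann_df <- do.call(rbind, lapply(anns, function(a) {
    row <- setNames(as.list(rep(NA_character_, length(fields))), fields)
    row[names(a)] <- lapply(a, as.character)
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  message(sprintf("read_structure_table: %d record(s) parsed from %s",
                  length(graphs), path))
  list(graphs = graphs, annotations = ann_df)
}

# "> <tag>" data fields of one SDF record, as a named list.
sdf_data_fields <- function(rec) {
  out <- list()
  hits <- grep("^>\\s*<", rec)
  for (h in hits) {
    tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", rec[h])
    val <- if (h + 1 <= length(rec)) trimws(rec[h + 1]) else ""
    out[[tag]] <- val
  }
  out
}
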