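#' Atomic property assignment
#'
#' Eight per-atom properties weight the quadratic indices: Ghose-Crippen
#' style hydrophobicity (HYD), partial charge (CHR), Pauling
#' electronegativity (E), atomic mass (M), polarizability (POL), polar
#' surface area contribution (PSA), molar refractivity (R) and van der
#' Waals volume (VDW). All but CHR are table-driven by (element,
#' environment class); CHR comes from an iterative
#' electronegativity-equalisation (Gasteiger-type) scheme.
#'
#' @name atomic-properties
NULL

PROPERTY_NAMES <- c("HYD", "CHR", "E", "M", "POL", "PSA", "R", "VDW")

.mtq_cache <- new.env(parent = emptyenv())

#' Load the built-in (or a user-supplied) property table set
#'
#' Each table is a CSV with columns `element`, `environment`, `value`;
#' `environment = "*"` is the element-level fallback. A `manifest.json`
#' records units, source tag and version.
#'
#' @param dir directory holding `<PROP>.csv` files and `manifest.json`.
#'   Defaults to the versioned tables shipped with the package.
#' @return list with `tables` (named list of data.frames) and `manifest`.
#' @export
load_property_tables <- function(dir = NULL) {
  if (is.null(dir)) {
    if (!is.null(.mtq_cache$tables)) return(.mtq_cache$tables)
    dir <- system.file("extdata", "property_tables", package = "mtqsar")
  }
  props <- setdiff(PROPERTY_NAMES, "CHR")
  tabs <- list()
  for (p in props) {
    f <- file.path(dir, paste0(p, ".csv"))
    if (!file.exists(f)) {
      mtq_stop("mtqsar_io_error", sprintf("missing property table %s", f))
    }
    tabs[[p]] <- read.csv(f, stringsAsFactors = FALSE)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list(tables = tabs, manifest = manifest)
  if (identical(dir, system.file("extdata", "property_tables",
                                 package = "mtqsar"))) {
    .mtq_cache$tables <- out
  }
  out
}

# Environment class per atom for a given property. The vocabulary is
# defined here and mirrored in the shipped CSV tables.
property_env_class <- function(prop, element, nH, aromatic, max_order) {
  if (prop == "PSA") {
    if (element == "N") {
      if (aromatic) return(if (nH > 0) "arH" else "ar")
      if (max_order >= 3) return("sp")
      if (max_order == 2) return(paste0("sp2H", min(nH, 2L)))
      return(paste0("sp3H", min(nH, 2L)))
    }
    if (element == "O") {
      if (aromatic) return("ar")
      if (max_order >= 2) return("dbl")
      if (nH > 0) return("OH")
      return("eth")
    }
    if (element == "S") {
      if (aromatic) return("ar")
      if (max_order >= 2) return("dbl")
      if (nH > 0) return("SH")
      return("thio")
    }
    return("*")
  }
  if (prop == "HYD") return(if (aromatic) "ar" else "al")
  "*"
}

lookup_property <- function(tab, prop, element, env_class, atom_idx) {
  hit <- tab$value[tab$element == element & tab$environment == env_class]
  if (length(hit) == 0) {
    hit <- tab$value[tab$element == element & tab$environment == "*"]
  }
  if (length(hit) == 0) {
    mtq_stop("mtqsar_property_error", sprintf(
      "element '%s' (atom %d) not covered by property table %s",
      element, atom_idx, prop))
  }
  hit[1]
}

# Gasteiger-type PEOE parameters a + b*q + c*q^2 per (element, hybridisation)
GASTEIGER_PARAMS <- local({
  m <- rbind(
    H_sp3  = c(7.17, 6.24, -0.56),
    C_sp3  = c(7.98, 9.18, 1.88),
    C_sp2  = c(8.79, 9.32, 1.51),
    C_sp   = c(10.39, 9.45, 0.73),
    N_sp3  = c(11.54, 10.82, 1.36),
    N_sp2  = c(12.87, 11.15, 0.85),
    N_sp   = c(15.68, 11.70, -0.27),
    O_sp3  = c(14.18, 12.92, 1.39),
    O_sp2  = c(17.07, 13.79, 0.47),
    F_sp3  = c(14.66, 13.85, 2.31),
    Cl_sp3 = c(11.00, 9.69, 1.35),
    Br_sp3 = c(10.08, 8.47, 1.16),
    I_sp3  = c(9.90, 7.96, 0.96),
    S_sp3  = c(10.14, 9.13, 1.38),
    S_sp2  = c(10.88, 9.49, 1.33),
    P_sp3  = c(8.90, 8.24, 0.96),
    Si_sp3 = c(9.19, 8.24, 0.86),
    B_sp3  = c(7.98, 8.16, 1.12))
  colnames(m) <- c("a", "b", "c")
  m
})

#' Iterative electronegativity-equalisation partial charges
#'
#' A deterministic Gasteiger-type scheme: atoms (including implicit
#' hydrogens, treated as pseudo-atoms) start from their formal charges;
#' for a fixed 8 iterations, charge flows along each bond from the less to
#' the more electronegative end, damped by 0.5 per iteration, with the
#' transfer scaled by the cation electronegativity of the donor atom.
#' Hydrogen charges are folded into their heavy atom at the end, so the
#' per-heavy-atom charges sum to the net formal charge of the molecule.
#'
#' @param g a `mol_graph`.
#' @param iterations,damping scheme constants (fixed defaults 8 and 0.5).
#' @return Numeric vector of partial charges, one per heavy atom.
#' @export
gasteiger_charges <- function(g, iterations = 8L, damping = 0.5) {
  n <- n_atoms(g)
  mb <- max_bond_order(g)
  hyb <- ifelse(mb >= 3, "sp", ifelse(mb == 2, "sp2", "sp3"))
  keys <- paste(g$atoms$element, hyb, sep = "_")
  fallback <- paste(g$atoms$element, "sp3", sep = "_")
  bad <- !(keys %in% rownames(GASTEIGER_PARAMS))
  keys[bad] <- fallback[bad]
  still_bad <- which(!(keys %in% rownames(GASTEIGER_PARAMS)))
  if (length(still_bad) > 0) {
    mtq_stop("mtqsar_property_error", sprintf(
      "element '%s' (atom %d) has no charge parameters",
      g$atoms$element[still_bad[1]], still_bad[1]))
  }
  # pseudo-atom list: heavy atoms then one H per implicit hydrogen
  nh <- g$atoms$nH
  nH_tot <- sum(nh)
  ntot <- n + nH_tot
  par <- matrix(0, ntot, 3)
  par[seq_len(n), ] <- GASTEIGER_PARAMS[keys, , drop = FALSE]
  if (nH_tot > 0) {
    par[(n + 1):ntot, ] <- matrix(GASTEIGER_PARAMS["H_sp3", ],
                                  nH_tot, 3, byrow = TRUE)
  }
  ei <- c(g$bonds$i, rep(seq_len(n), nh))
  ej <- c(g$bonds$j, if (nH_tot > 0) (n + 1):ntot else integer())
  q <- c(as.numeric(g$atoms$charge), rep(0, nH_tot))
  h_owner <- rep(seq_len(n), nh)
  chi_plus <- par[, 1] + par[, 2] + par[, 3]
  chi_plus[chi_plus <= 0] <- 1
  # hydrogen cation electronegativity: conventional special value
  if (nH_tot > 0) chi_plus[(n + 1):ntot] <- 20.02
  for (t in seq_len(iterations)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    d <- damping^t
    dq <- rep(0, ntot)
    for (b in seq_along(ei)) {
      a1 <- ei[b]; a2 <- ej[b]
      if (chi[a1] == chi[a2]) next
      if (chi[a1] < chi[a2]) { lo <- a1; hi <- a2 } else { lo <- a2; hi <- a1 }
      tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * d
      dq[lo] <- dq[lo] + tr
      dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }
  heavy_q <- q[seq_len(n)]
  if (nH_tot > 0) {
    for (k in seq_len(nH_tot)) {
      heavy_q[h_owner[k]] <- heavy_q[h_owner[k]] + q[n + k]
    }
  }
  heavy_q
}

#' Assign the eight atomic property vectors to a molecule
#'
#' @param g a `mol_graph`.
#' @param tables property table set from [load_property_tables()].
#' @param properties subset of property names to assign.
#' @return Matrix (heavy atoms x properties) with columns named
#'   `HYD, CHR, E, M, POL, PSA, R, VDW` (or the requested subset).
#' @export
assign_properties <- function(g, tables = load_property_tables(),
                              properties = PROPERTY_NAMES) {
  stopifnot(all(properties %in% PROPERTY_NAMES))
  n <- n_atoms(g)
  arom <- aromatic_flags(g)
  mb <- max_bond_order(g)
  out <- matrix(NA_real_, n, length(properties),
                dimnames = list(NULL, properties))
  for (p in properties) {
    if (p == "CHR") {
      out[, p] <- gasteiger_charges(g)
      next
    }
    tab <- tables$tables[[p]]
    for (a in seq_len(n)) {
      el <- g$atoms$element[a]
      env <- property_env_class(p, el, g$atoms$nH[a], arom[a], mb[a])
      v <- lookup_property(tab, p, el, env, a)
      if (p == "HYD") v <- v + g$atoms$nH[a] *
          lookup_property(tab, p, "H", "*", a)
      out[a, p] <- v
    }
  }
  if ("M" %in% properties && any(out[, "M"] <= 0)) {
    mtq_stop("mtqsar_property_error", "non-positive atomic mass")
  }
  out
}
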