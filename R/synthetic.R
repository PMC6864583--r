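#' Synthetic condition-annotated datasets with a planted
#' structure-activity relationship
#'
#' The generator emulates the shape of a curated kinase-inhibition
#' dataset: drug-like molecules assembled from a ring/linker/substituent
#' grammar, each assayed under one or more of four experimental
#' conditions (two biological targets x two effectiveness measures), with
#' a roughly one-third active class at the 500 nM cut-off. Activity is
#' driven by a planted logistic rule on true computed quadratic-index
#' descriptors with condition-specific intercepts, so descriptor
#' recovery, Box-Jenkins benefit and screening enrichment are all
#' well-defined quantities.
#'
#' @name synthetic-data
NULL

# Grammar vocabulary. All pieces concatenate into valid SMILES: a prefix
# attaches to the first ring atom, suffixes/linkers to the last written
# ring atom.
SYNTH_RINGS <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "C1CCCCC1",
                 "C1CCNCC1", "C1CCOCC1", "c1ccsc1", "c1cc[nH]c1",
                 "C1CCNC1", "c1ccc2ccccc2c1")
SYNTH_LINKERS <- c("", "C", "CC", "CCC", "O", "OC", "N", "NC(=O)",
                   "C(=O)N", "S", "C=C", "C(=O)", "COC", "CCN")
SYNTH_PREFIX <- c("", "C", "CC", "N", "O", "F", "Cl", "OC", "NC")
SYNTH_SUFFIX <- c("", "C", "CC", "O", "N", "F", "Cl", "Br", "C(F)(F)F",
                  "C#N", "C(=O)O", "C(=O)N", "OC", "N(C)C", "CO")

#' Generate drug-like molecules from a fragment grammar
#'
#' Molecules are 1-3 ring systems joined by linkers with optional terminal
#' substituents, 10-40 heavy atoms, valence-legal by construction, and
#' byte-identical across runs for a fixed seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param ids identifier prefix (default "syn").
#' @return list of `mol_graph` (each carries its SMILES).
#' @export
generate_molecules <- function(n, seed = 1L, ids = "syn") {
  stopifnot(n >= 1)
  smiles <- with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        n_rings <- sample(1:3, 1, prob = c(0.25, 0.5, 0.25))
        s <- sample(SYNTH_PREFIX, 1)
        s <- paste0(s, sample(SYNTH_RINGS, 1))
        if (n_rings >= 2) {
          s <- paste0(s, sample(SYNTH_LINKERS, 1), sample(SYNTH_RINGS, 1))
        }
        if (n_rings >= 3) {
          s <- paste0(s, sample(SYNTH_LINKERS, 1), sample(SYNTH_RINGS, 1))
        }
        s <- paste0(s, sample(SYNTH_SUFFIX, 1))
        # heavy atom count straight from the string (grammar atoms are
        # single-letter or bracketed single-heavy-atom tokens)
        nh <- nchar(gsub("[^A-Za-z]", "", gsub("\\[nH\\]", "n", s))) -
          nchar(gsub("[^l]", "", s)) - nchar(gsub("[^r]", "", s))
        if (nh >= 10 && nh <= 40) break
      }
      out[i] <- s
    }
    out
  })
  parse_smiles_batch(smiles, ids = paste0(ids, seq_len(n)),
                     strict = TRUE)$graphs
}

#' Specification of a synthetic condition-annotated dataset
#'
#' @param n_compounds number of distinct molecules.
#' @param conditions condition table ([default_conditions()]).
#' @param planted_descriptors descriptor names carrying the signal; must
#'   exist under `cfg` and have non-degenerate variance over the grammar
#'   (geometric-mean aggregates of sparse properties such as PSA collapse
#'   to zero and are unusable here).
#' @param planted_coefficients base standardised coefficients (unit lead
#'   by default; the overall signal strength is `effect_scale` times
#'   these, so `effect_scale = 3` plants a lead standardised coefficient
#'   of 3 and `effect_scale = 0` is the null condition).
#' @param condition_intercepts per-condition shift of the latent activity
#'   (named by condition id); these make activity genuinely
#'   condition-dependent, which is what the Box-Jenkins deviations must
#'   recover.
#' @param effect_scale multiplier on the planted coefficients (0 = pure
#'   noise).
#' @param noise_scale scale of the latent logistic noise.
#' @param active_fraction target overall active fraction (default 1/3,
#'   achieved by calibrating a global intercept).
#' @param condition_prob probability that a compound is assayed under
#'   each condition (at least one is guaranteed).
#' @param cfg descriptor configuration used to compute the planted
#'   descriptors.
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 500L,
                           conditions = default_conditions(),
                           planted_descriptors = c("Tnsq2(HYD)N1",
                                                   "Tssq2(CH)RA",
                                                   "Tnsq2(PSA)MX",
                                                   "Tnsq0(M)N1"),
                           planted_coefficients = c(1, -0.67, 0.5, -0.33),
                           condition_intercepts = c(c1 = 1, c2 = 0.3,
                                                    c3 = -0.3, c4 = -1),
                           effect_scale = 3, noise_scale = 0.5,
                           active_fraction = 1 / 3,
                           condition_prob = 0.5,
                           cfg = quadratic_config(k_max = 5L),
                           seed = 1L) {
  stopifnot(length(planted_descriptors) == length(planted_coefficients),
            active_fraction > 0, active_fraction < 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 conditions = conditions,
                 planted_descriptors = planted_descriptors,
                 planted_coefficients = planted_coefficients,
                 condition_intercepts = condition_intercepts,
                 effect_scale = effect_scale, noise_scale = noise_scale,
                 active_fraction = active_fraction,
                 condition_prob = condition_prob, cfg = cfg, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic condition-annotated dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (data.frame: id, smiles, condition, bt,
#'   me, activity_nM, label), `graphs` (one per compound), `eta` (latent
#'   per-compound signal) and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  graphs <- generate_molecules(spec$n_compounds, seed = spec$seed)
  D <- compute_descriptor_matrix(graphs, spec$cfg)
  miss <- setdiff(spec$planted_descriptors, colnames(D))
  if (length(miss) > 0) {
    mtq_stop("mtqsar_synth_error", paste(
      "planted descriptor(s) absent under the descriptor config:",
      paste(miss, collapse = ", ")))
  }
  Z <- standardise_columns(D[, spec$planted_descriptors, drop = FALSE])
  eta <- drop(Z %*% (spec$planted_coefficients * spec$effect_scale))
  out <- with_seed(spec$seed + 1L, {
    nC <- nrow(spec$conditions)
    rows <- list()
    for (i in seq_len(spec$n_compounds)) {
      take <- runif(nC) < spec$condition_prob
      if (!any(take)) take[sample.int(nC, 1)] <- TRUE
      for (ci in which(take)) {
        rows[[length(rows) + 1]] <- c(i, ci)
      }
    }
    m <- do.call(rbind, rows)
    lin <- eta[m[, 1]] +
      spec$condition_intercepts[spec$conditions$condition[m[, 2]]]
    # calibrate a global intercept so the mean activity probability hits
    # the target active fraction
    f <- function(d) mean(plogis((lin + d) / spec$noise_scale)) -
      spec$active_fraction
    delta <- uniroot(f, c(-50, 50))$root
    p <- plogis((lin + delta) / spec$noise_scale)
    active <- runif(length(p)) < p
    achieved <- mean(active)
    # binomial noise dominates at small n; widen the guard accordingly
    tol <- max(0.05, 3 * sqrt(spec$active_fraction *
                                (1 - spec$active_fraction) / length(active)))
    if (abs(achieved - spec$active_fraction) > tol) {
      mtq_stop("mtqsar_synth_error", sprintf(
        "achieved active fraction %.3f too far from target %.3f",
        achieved, spec$active_fraction))
    }
    # log-uniform activity on the class-consistent side of 500 nM
    act_nM <- ifelse(active,
                     10^runif(length(p), log10(0.1), log10(500)),
                     10^runif(length(p), log10(500) + 1e-6, 6))
    data.frame(
      id = vapply(graphs[m[, 1]], function(g) g$id, character(1)),
      smiles = vapply(graphs[m[, 1]], function(g) g$smiles, character(1)),
      condition = spec$conditions$condition[m[, 2]],
      bt = spec$conditions$bt[m[, 2]],
      me = spec$conditions$me[m[, 2]],
      activity_nM = act_nM,
      stringsAsFactors = FALSE)
  })
  out$label <- label_activity(out$activity_nM)
  list(records = out, graphs = graphs, eta = eta, spec = spec)
}

#' Write a synthetic dataset to the standard dataset CSV
#'
#' @param dataset result of [generate_dataset()].
#' @param path CSV path; the generator specification is saved as `<path>.spec.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(dataset$records, path, row.names = FALSE)
  sp <- dataset$spec
  jsonlite::write_json(
    list(n_compounds = sp$n_compounds,
         conditions = sp$conditions,
         planted_descriptors = sp$planted_descriptors,
         planted_coefficients = sp$planted_coefficients,
         condition_intercepts = as.list(sp$condition_intercepts),
         effect_scale = sp$effect_scale, noise_scale = sp$noise_scale,
         active_fraction = sp$active_fraction,
         condition_prob = sp$condition_prob, seed = sp$seed,
         descriptor_config = unclass(sp$cfg)),
    paste0(path, ".spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
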