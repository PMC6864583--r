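# Shared fixtures and independent oracles. Oracles are deliberately
# written in the most naive way possible (enumeration, direct formula
# evaluation) and never call the code paths they check.

# --- direct graph constructors (no SMILES round trip needed) ----------

mk_graph <- function(n, edges, element = "C") {
  bonds <- if (length(edges)) {
    data.frame(i = vapply(edges, `[`, numeric(1), 1),
               j = vapply(edges, `[`, numeric(1), 2), order = 1L)
  } else data.frame(i = integer(), j = integer(), order = integer())
  mol_graph(atoms = data.frame(element = rep(element, n),
                               charge = 0L, nH = 0L),
            bonds = bonds, id = sprintf("g%d", n))
}

mk_path <- function(n) {
  mk_graph(n, if (n > 1) lapply(seq_len(n - 1), function(i) c(i, i + 1))
           else list())
}

mk_cycle <- function(n) {
  mk_graph(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                list(c(n, 1))))
}

random_graph <- function(n, p_edge = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  take <- runif(nrow(pairs)) < p_edge
  # no isolated atoms: attach each to a random partner
  edges <- pairs[take, , drop = FALSE]
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  for (v in which(deg == 0)) {
    w <- sample(setdiff(seq_len(n), v), 1)
    edges <- rbind(edges, c(min(v, w), max(v, w)))
  }
  edges <- unique(edges)
  mk_graph(n, lapply(seq_len(nrow(edges)), function(r) edges[r, ]))
}

# --- oracles ----------------------------------------------------------

# count length-k walks i -> j by explicit enumeration
brute_walks <- function(A, k, i, j) {
  if (k == 0) return(as.numeric(i == j))
  total <- 0
  for (v in which(A[i, ] > 0)) {
    total <- total + brute_walks(A, k - 1, v, j)
  }
  total
}

# pairwise AUC with half-credit for ties
auc_brute <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == -1)
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (scores[a] > scores[b]) 1 else if (scores[a] == scores[b])
      0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# the standardisation-approach AD rule evaluated directly on an s-vector
ad_rule_oracle <- function(s, threshold = 3, z = 1.28) {
  if (max(s) <= threshold) return(TRUE)
  if (min(s) > threshold) return(FALSE)
  (mean(s) + z * sd(s)) <= threshold
}

# nearest-centroid classification under pooled covariance (balanced
# classes, so priors cancel)
mahal_oracle <- function(X, y, Q) {
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m2 <- colMeans(X[y == -1, , drop = FALSE])
  W <- crossprod(sweep(X[y == 1, , drop = FALSE], 2, m1)) +
    crossprod(sweep(X[y == -1, , drop = FALSE], 2, m2))
  Sp <- W / (nrow(X) - 2)
  inv <- solve(Sp)
  apply(Q, 1, function(x) {
    d1 <- drop(t(x - m1) %*% inv %*% (x - m1))
    d2 <- drop(t(x - m2) %*% inv %*% (x - m2))
    if (d1 < d2) 1L else -1L
  })
}

# small cached set of parsed drug-like molecules for reuse across tests
fixture_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      smi <- c("c1ccccc1", "Cc1ccccc1", "CCO", "CC(=O)Nc1ccc(O)cc1",
               "c1ccncc1", "C1CCNCC1", "Clc1ccc(CN2CCOCC2)cc1",
               "O=C(O)c1ccccc1O", "CCN(CC)CCNC(=O)c1ccc(N)cc1",
               "c1ccc2ccccc2c1")
      cache <<- parse_smiles(smi, ids = paste0("fix", seq_along(smi)))
    }
    cache
  }
})

# records table helper for Box-Jenkins tests (RNG state restored)
mk_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    conds <- default_conditions()
    ci <- sample(nrow(conds), n, replace = TRUE)
    data.frame(id = paste0("r", seq_len(n)),
               bt = conds$bt[ci], me = conds$me[ci],
               condition = conds$condition[ci],
               label = sample(c(1L, -1L), n, replace = TRUE,
                              prob = c(0.4, 0.6)))
  })
}
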