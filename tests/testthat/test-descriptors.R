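test_that("structure matrices match their definitions", {
  p2 <- mk_path(2)
  expect_equal(structure_matrix(p2, "ns", 1), matrix(c(0, 1, 1, 0), 2))
  expect_equal(structure_matrix(p2, "ns", 0), diag(2))
  expect_error(structure_matrix(p2, "ns", -1),
               class = "mtqsar_descriptor_error")
  # stochastic powers stay row-stochastic
  benzene <- mk_cycle(6)
  for (k in c(1, 3, 7)) {
    expect_equal(unname(rowSums(structure_matrix(benzene, "ss", k))),
                 rep(1, 6))
  }
  # single atom: 1x1 identity for either kind
  expect_equal(structure_matrix(mk_graph(1, list()), "ss", 3), matrix(1))
})

test_that("matrix powers equal brute-force walk enumeration", {
  set.seed(7)
  checked <- 0
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    g <- random_graph(n)
    A <- adjacency_matrix(g)
    for (k in 0:4) {
      Mk <- structure_matrix(g, "ns", k)
      i <- sample(n, 1); j <- sample(n, 1)
      expect_equal(Mk[i, j], brute_walks(A, k, i, j))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 40)
})

test_that("shortest-path order semantics use the distance-k indicator", {
  p3 <- mk_path(3)
  M2 <- structure_matrix(p3, "ns", 2, k_semantics = "shortest_path_distance")
  expect_equal(M2, matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3))
  # walk powers differ: A^2 has nonzero diagonal (back-and-forth walks)
  expect_false(all(structure_matrix(p3, "ns", 2) == M2))
})

test_that("local quadratic indices expand the quadratic form", {
  p2 <- mk_path(2)
  expect_equal(local_quadratic_index(p2, "ns", 1, c(1, 1)), c(1, 1))
  expect_equal(total_index(local_quadratic_index(p2, "ns", 1, c(1, 1)), "N1"),
               2)
  # k = 0 reduces to squared properties
  g <- random_graph(5)
  x <- rnorm(5)
  expect_equal(local_quadratic_index(g, "ns", 0, x), x^2)
  # benzene with unit weights: every atom sees two neighbours
  benzene <- mk_cycle(6)
  expect_equal(local_quadratic_index(benzene, "ns", 1, rep(1, 6)), rep(2, 6))
  expect_equal(total_index(local_quadratic_index(benzene, "ns", 1, rep(1, 6)),
                           "N1"), 12)
})

test_that("total index aggregation operators match their formulas", {
  expect_equal(total_index(c(3, 4), "N1"), 7)
  expect_equal(total_index(c(3, 4), "N2"), 25)
  expect_equal(total_index(c(3, 4), "N2", n2_mode = "euclidean_norm"), 5)
  expect_equal(total_index(c(3, 4), "RA"), 1)
  expect_equal(total_index(c(3, 4), "MX"), 4)
  expect_equal(total_index(c(3, 4), "MN"), 3)
  expect_equal(total_index(c(3, 4), "GM"), sqrt(12), tolerance = 1e-12)
  # constant vectors
  expect_equal(total_index(rep(2.5, 7), "N1"), 17.5)
  expect_equal(total_index(rep(2.5, 7), "GM"), 2.5)
  expect_equal(total_index(rep(2.5, 7), "RA"), 0)
  # sign-preserving geometric mean, zero product, never NaN
  expect_equal(total_index(c(-2, -3), "GM"), sqrt(6))
  expect_equal(total_index(c(-2, 3), "GM"), -sqrt(6))
  expect_equal(total_index(c(0, 5), "GM"), 0)
  expect_false(is.nan(total_index(c(-1, 2, -3), "GM")))
})

test_that("descriptor values obey the property-scaling law", {
  set.seed(11)
  g <- random_graph(6)
  x <- rnorm(6) + 2
  a <- 1.7
  for (kind in c("ns", "ss")) {
    for (k in 0:3) {
      L1 <- local_quadratic_index(g, kind, k, x)
      L2 <- local_quadratic_index(g, kind, k, a * x)
      expect_equal(L2, a^2 * L1, tolerance = 1e-10)
      for (agg in c("N1", "GM", "RA", "MX", "MN")) {
        expect_equal(total_index(L2, agg), a^2 * total_index(L1, agg),
                     tolerance = 1e-9)
      }
      expect_equal(total_index(L2, "N2"), a^4 * total_index(L1, "N2"),
                   tolerance = 1e-9)
    }
  }
})

test_that("total indices are invariant under atom relabelling", {
  set.seed(3)
  g <- random_graph(7)
  x <- rnorm(7) + 1
  perm <- sample(7)
  inv <- order(perm)
  remap <- g$bonds
  remap$i <- inv[g$bonds$i]; remap$j <- inv[g$bonds$j]
  gp <- mol_graph(atoms = g$atoms[perm, ], bonds = remap, id = "p")
  for (kind in c("ns", "ss")) for (k in c(1, 2, 4)) {
    L <- local_quadratic_index(g, kind, k, x)
    Lp <- local_quadratic_index(gp, kind, k, x[perm])
    for (agg in c("N1", "N2", "GM", "RA", "MX", "MN")) {
      expect_equal(total_index(Lp, agg), total_index(L, agg),
                   tolerance = 1e-9)
    }
  }
})

test_that("descriptor matrices have canonical names, shape and determinism", {
  expect_equal(descriptor_name("ns", 13, "VDW", "N2"), "Tnsq13(VDW)N2")
  expect_equal(descriptor_name("ss", 11, "CHR", "MN"), "Tssq11(CH)MN")
  graphs <- fixture_graphs()[c(1, 3)]
  cfg <- quadratic_config(k_max = 1, kinds = "ns", properties = "M",
                          aggregations = c("N1", "MX"))
  D <- compute_descriptor_matrix(graphs, cfg)
  expect_equal(dim(D), c(2, 4))   # 2 orders x 1 property x 2 aggregations
  expect_equal(colnames(D), c("Tnsq0(M)N1", "Tnsq0(M)MX",
                              "Tnsq1(M)N1", "Tnsq1(M)MX"))
  expect_false(anyDuplicated(colnames(D)) > 0)
  # duplicated molecules give identical rows
  D2 <- compute_descriptor_matrix(graphs[c(1, 1)], cfg)
  expect_equal(unname(D2[1, ]), unname(D2[2, ]))
  # full column count formula
  cfg_full <- quadratic_config(k_max = 3)
  Df <- compute_descriptor_matrix(graphs[1], cfg_full)
  expect_equal(ncol(Df), 2 * 4 * 8 * 6)
  expect_true(all(is.finite(Df)))
})

test_that("descriptor matrices survive the CSV + sidecar round trip", {
  graphs <- fixture_graphs()[1:3]
  cfg <- quadratic_config(k_max = 2, kinds = "ns",
                          properties = c("M", "E"))
  D <- compute_descriptor_matrix(graphs, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_matrix(D, path)
  D2 <- read_descriptor_matrix(path)
  expect_equal(unname(as.matrix(D2)), unname(as.matrix(D)),
               tolerance = 1e-9)
  expect_equal(colnames(D2), colnames(D))
  expect_equal(attr(D2, "config")$k_max, 2L)
})
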