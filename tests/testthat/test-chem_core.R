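test_that("SMILES parsing yields correct hydrogen-suppressed graphs", {
  g <- parse_smiles("C")
  expect_equal(n_atoms(g), 1)
  expect_equal(nrow(g$bonds), 0)
  expect_equal(g$atoms$nH, 4L)

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(benzene), 6)
  expect_equal(nrow(benzene$bonds), 6)
  expect_equal(unname(rowSums(adjacency_matrix(benzene))), rep(2, 6))

  ethanol <- parse_smiles("CCO")
  expect_equal(n_atoms(ethanol), 3)
  expect_equal(nrow(ethanol$bonds), 2)
  expect_equal(sort(rowSums(adjacency_matrix(ethanol))), c(1, 1, 2))

  A <- adjacency_matrix(benzene)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
})

test_that("parse failures carry a token position; multi-fragment input needs the flag", {
  err <- tryCatch(parse_smiles("C1CC"), error = identity)
  expect_s3_class(err, "mtqsar_parse_error")
  expect_match(conditionMessage(err), "position")
  expect_match(conditionMessage(err), "ring bond")

  err2 <- tryCatch(parse_smiles("CC(C"), error = identity)
  expect_match(conditionMessage(err2), "unclosed")

  expect_error(parse_smiles("CC(=O)[O-].[Na+]"), class = "mtqsar_parse_error")
  g <- parse_smiles("CC(=O)[O-].[Na+]", keep_largest_fragment = TRUE)
  expect_equal(n_atoms(g), 4)        # acetate, sodium stripped
  expect_equal(sum(g$atoms$charge), -1L)
})

test_that("parse/write round trip preserves the graph up to relabelling", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1",
                "Clc1ccc(CN2CCOCC2)cc1", "c1cc[nH]c1")) {
    g <- parse_smiles(smi)
    g2 <- parse_smiles(write_smiles(g, canonical = TRUE))
    expect_equal(sort(table(g2$atoms$element)), sort(table(g$atoms$element)),
                 info = smi)
    expect_equal(nrow(g2$bonds), nrow(g$bonds), info = smi)
    expect_equal(sort(rowSums(adjacency_matrix(g2))),
                 sort(rowSums(adjacency_matrix(g))), info = smi)
    expect_equal(sum(g2$atoms$nH), sum(g$atoms$nH), info = smi)
  }
})

test_that("property assignment covers the 8 properties and respects structure", {
  g <- parse_smiles("CCO")
  P <- assign_properties(g)
  expect_equal(colnames(P), c("HYD", "CHR", "E", "M", "POL", "PSA", "R", "VDW"))
  expect_equal(nrow(P), 3)
  expect_equal(unname(P[1, "M"]), 12.011)
  expect_equal(unname(P[3, "M"]), 15.999)
  expect_true(all(P[, "M"] > 0))
  expect_true(all(P[, "VDW"] > 0))
  expect_true(all(P[, "PSA"] >= 0))
  # ethane: no polar atoms, PSA contributions all zero
  expect_equal(unname(assign_properties(parse_smiles("CC"))[, "PSA"]),
               c(0, 0))
  # methane mass example
  expect_equal(unname(assign_properties(parse_smiles("C"))[, "M"]), 12.011)
})

test_that("partial charges sum to the net formal charge", {
  expect_lt(abs(sum(gasteiger_charges(parse_smiles("CCO")))), 1e-6)
  expect_lt(abs(sum(gasteiger_charges(parse_smiles("CC(=O)Nc1ccc(O)cc1")))),
            1e-6)
  expect_lt(abs(sum(gasteiger_charges(parse_smiles("C[N+](C)(C)C"))) - 1),
            1e-6)
  # deterministic
  g <- parse_smiles("c1ccncc1")
  expect_identical(gasteiger_charges(g), gasteiger_charges(g))
})

test_that("property assignment is permutation-equivariant", {
  g <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  n <- n_atoms(g)
  set.seed(42)
  perm <- sample(n)
  inv <- order(perm)
  remap <- g$bonds
  remap$i <- inv[g$bonds$i]; remap$j <- inv[g$bonds$j]
  gp <- mol_graph(atoms = g$atoms[perm, ], bonds = remap, id = "perm")
  P <- assign_properties(g)
  Pp <- assign_properties(gp)
  expect_equal(unname(Pp), unname(P[perm, ]), tolerance = 1e-12)
})

test_that("uncovered elements raise a structured error naming the property", {
  g <- parse_smiles("C[Se]C")
  err <- tryCatch(assign_properties(g), error = identity)
  expect_s3_class(err, "mtqsar_property_error")
  expect_match(conditionMessage(err), "Se")
})

test_that("parsed graphs agree with an independent cheminformatics toolkit", {
  skip_if_not_installed("ChemmineR")
  for (smi in c("CCO", "c1ccncc1", "CC(=O)Nc1ccc(O)cc1")) {
    g <- parse_smiles(smi)
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    expect_equal(n_atoms(g), nrow(ab), info = smi)
    expect_equal(nrow(g$bonds), nrow(bb), info = smi)
    elements <- sort(sub("_.*$", "", rownames(ab)))
    expect_equal(sort(g$atoms$element), elements, info = smi)
  }
})

test_that("structure tables are read from .smi, CSV and SDF", {
  smi_file <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "CCN amine"), smi_file)
  suppressMessages(res <- read_structure_table(smi_file))
  expect_length(res$graphs, 3)
  expect_equal(res$annotations$id, c("ethanol", "benzene", "amine"))

  csv_file <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CCC"),
                       activity_nM = c(10, 900)), csv_file, row.names = FALSE)
  suppressMessages(res2 <- read_structure_table(csv_file, format = "csv"))
  expect_length(res2$graphs, 2)
  expect_equal(res2$annotations$activity_nM, c(10, 900))

  # SDF with a data field
  sdf_file <- withr::local_tempfile(fileext = ".sdf")
  g <- parse_smiles("CCO", ids = "eth")
  block <- mtqsar:::graph_to_sdf_text(g)
  block <- append(block, c("> <Activity>", "123", ""),
                  after = which(block == "M  END"))
  writeLines(block, sdf_file)
  suppressMessages(res3 <- read_structure_table(sdf_file, format = "sdf"))
  expect_length(res3$graphs, 1)
  expect_equal(n_atoms(res3$graphs[[1]]), 3)
  expect_equal(res3$annotations$Activity, "123")

  # empty file: empty result with a warning
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(), empty)
  expect_warning(res4 <- read_structure_table(empty), "empty")
  expect_length(res4$graphs, 0)

  # lenient mode skips bad records with a warning
  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ok", "C1CC broken", "CCC ok2"), bad)
  suppressMessages(expect_warning(res5 <- read_structure_table(bad),
                                  "skipped"))
  expect_length(res5$graphs, 2)
  expect_error(
    suppressMessages(read_structure_table(bad, strict = TRUE)),
    class = "mtqsar_parse_error")
})
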