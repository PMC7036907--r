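test_that("SMILES parse into correct heavy-atom graphs", {
  g <- smiles_to_graph("CCO")
  expect_equal(g$n_atoms, 3)
  expect_equal(sort(g$degrees), c(1, 1, 2))
  expect_equal(g$degrees[2], 2)           # central carbon
  expect_equal(g$n_h, c(3, 2, 1))

  b <- smiles_to_graph("c1ccccc1")
  expect_equal(b$n_atoms, 6)
  expect_true(all(b$degrees == 2))
  expect_true(all(b$aromatic))

  # neighbor symmetry and degree consistency on a branched molecule
  m <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1")
  for (v in seq_len(m$n_atoms)) {
    expect_equal(length(m$neighbors[[v]]), m$degrees[v])
    for (u in m$neighbors[[v]]) expect_true(v %in% m$neighbors[[u]])
  }
  expect_equal(ncol(m$atom_features), atom_feature_spec()$feature_dim)
})

test_that("malformed and empty SMILES are rejected with the offending string", {
  expect_error(smiles_to_graph("C("), "C\\(")
  expect_error(smiles_to_graph("C1CC"), "unparseable")
  expect_error(smiles_to_graph(""), "unparseable")
  expect_error(parse_molecules(c("CC", "CCX")), "unparseable")
  expect_error(smiles_to_graph("[H][H]"), "no heavy atoms")
})

test_that("multi-fragment (salt) SMILES stay one graph with components", {
  g <- smiles_to_graph("[Na+].[O-]C(=O)C")
  expect_equal(g$n_atoms, 5)
  expect_equal(g$degrees[g$elements == "Na"], 0)
  expect_equal(sum(g$charge), 0)          # +1 and -1
})

test_that("atom feature vectors encode element, degree, hydrogens, aromaticity", {
  spec <- atom_feature_spec()
  g <- smiles_to_graph("CCO")
  v <- g$atom_features[1, ]               # terminal carbon
  expect_equal(length(v), spec$feature_dim)
  expect_equal(v[seq_along(spec$elements)],
               as.numeric(spec$elements == "C"))
  deg_block <- v[length(spec$elements) + seq_len(7)]
  expect_equal(deg_block, as.numeric(0:6 == 1))
  b <- smiles_to_graph("c1ccccc1")
  arom_flag_pos <- length(spec$elements) + 7 + 5 + 1
  expect_equal(b$atom_features[1, arom_flag_pos], 1)
  expect_equal(g$atom_features[1, arom_flag_pos], 0)
  # unknown element falls into "other"
  se <- smiles_to_graph("[SeH2]")
  expect_equal(se$atom_features[1, which(spec$elements == "other")], 1)
})

test_that("re-canonicalized graphs are isomorphic to the original", {
  smis <- c("OCC", "c1ccc(cc1)C", "CC(=O)OC", "C1CC1CO")
  for (s in smis) {
    g1 <- smiles_to_graph(s)
    g2 <- smiles_to_graph(canonical_smiles(s))
    expect_equal(sort(g1$degrees), sort(g2$degrees))
    expect_equal(g1$n_atoms, g2$n_atoms)
    f1 <- apply(g1$atom_features, 1, paste, collapse = ",")
    f2 <- apply(g2$atom_features, 1, paste, collapse = ",")
    expect_equal(sort(f1), sort(f2))
  }
})

test_that("compound labels are assembled as the union over herbs", {
  herb_labels <- data.frame(
    herb_id = c("h1", "h2"),
    liver = c(1L, 0L), stomach = c(1L, 0L), lung = c(0L, 1L))
  herb_compounds <- data.frame(
    herb_id = c("h1", "h1", "h1", "h2", "h3"),
    compound_id = c("c1", "c2", "c3", "c1b", "c9"),
    smiles = c("CCO", "CCC", "CCCC", "OCC", "CCCCCC"))
  lm <- assemble_compound_labels(herb_labels, herb_compounds)
  # c1 ("CCO") and c1b ("OCC") merge by canonical SMILES; h3 has no labels
  expect_equal(nrow(lm$labels), 3)
  eth <- which(lm$smiles == canonical_smiles("CCO"))
  expect_equal(unname(lm$labels[eth, ]), c(1L, 1L, 1L))   # union of h1, h2
  others <- setdiff(seq_len(3), eth)
  for (r in others) expect_equal(unname(lm$labels[r, ]), c(1L, 1L, 0L))
  expect_error(
    assemble_compound_labels(herb_labels,
                             data.frame(herb_id = "hX", compound_id = "z",
                                        smiles = "C")),
    "no labeled compounds")
})

test_that("compound tables and .smi files round-trip through disk", {
  lm <- label_matrix(c("a", "b"), c("CCO", "c1ccccc1"),
                     matrix(c(1L, 0L, 0L, 1L), 2), c("liver", "lung"))
  path <- tempfile(fileext = ".csv")
  write_compound_table(lm, path)
  lm2 <- read_compound_table(path)
  expect_equal(lm2$labels, lm$labels)
  expect_equal(lm2$smiles, lm$smiles)

  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2", "CC"), smi)
  rs <- read_smi(smi)
  expect_equal(unname(rs), c("CCO", "c1ccccc1", "CC"))
  expect_equal(names(rs)[1:2], c("mol1", "mol2"))
})
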