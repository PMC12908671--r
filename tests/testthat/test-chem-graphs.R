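test_that("atom featurization produces the fixed 45-wide block layout", {
  sp3_carbon <- list(element = "C", degree = 4, formal_charge = 0,
                     radical_electrons = 0, hybridization = "sp3",
                     is_aromatic = FALSE, num_h = 0, chirality = "other")
  v <- featurize_atom(sp3_carbon, c(1, 2, 3))
  expect_length(v, 45)
  expect_equal(sum(vapply(mol_node_blocks(), affipose:::block_width, 1L)), 45L)
  expect_equal(v[1], 1)                       # C is the first atom-type slot
  expect_equal(v[18:20], c(1, 2, 3) / 10)     # scaled coordinates
  expect_equal(v[30 + 2], 1)                  # sp3 is third hybridization slot
  # Se falls into the catch-all atom-type slot
  se <- featurize_atom(list(element = "Se"), c(0, 0, 0))
  expect_equal(se[17], 1)
  expect_equal(sum(se[1:17]), 1)
  # unknown hybridization maps to "other", never errors
  odd <- featurize_atom(list(element = "C", hybridization = "sp3d4"), c(0, 0, 0))
  expect_equal(odd[35], 1)
  expect_error(featurize_atom(list(element = "C"), c(0, NA, 0)),
               class = "affipose_invalid_input")
  expect_error(featurize_atom(list(element = ""), c(0, 0, 0)),
               class = "affipose_invalid_input")
})

test_that("bond featurization covers the four blocks and rejects unknown types", {
  arom <- featurize_bond(list(type = "aromatic", conjugated = TRUE,
                              in_ring = TRUE, stereo = "none"))
  expect_length(arom, 12)
  expect_equal(which(arom[1:4] == 1), 4L)
  expect_equal(which(arom[5:6] == 1), 2L)
  expect_equal(which(arom[7:8] == 1), 2L)
  expect_equal(which(arom[9:12] == 1), 1L)
  plain <- featurize_bond(list(type = "single", conjugated = FALSE,
                               in_ring = FALSE, stereo = "StereoNone"))
  expect_equal(sum(plain), 4)                 # one hot per block
  e_bond <- featurize_bond(list(type = "double", conjugated = TRUE,
                                in_ring = FALSE, stereo = "StereoE"))
  expect_equal(e_bond[12], 1)
  z_bond <- featurize_bond(list(type = "double", stereo = "Z"))
  expect_equal(z_bond[11], 1)
  any_bond <- featurize_bond(list(type = "double", stereo = "StereoAny"))
  expect_equal(any_bond[10], 1)
  expect_error(featurize_bond(list(type = "quadruple")),
               class = "affipose_invalid_input")
})

test_that("node vector decomposition inverts the featurizer layout", {
  n_atom <- list(element = "N", degree = 3, formal_charge = 0,
                 radical_electrons = 0, hybridization = "sp3",
                 is_aromatic = FALSE, num_h = 1, chirality = "other")
  d <- decompose_mol_node_vector(featurize_atom(n_atom, c(0.5, -1, 2)))
  expect_equal(d$labels$atom_type, "N")
  expect_equal(d$labels$degree, "3")
  expect_equal(d$labels$num_h, "1")
  expect_equal(d$scalars$position, c(0.5, -1, 2))
  expect_length(d$problems, 0)
  zeros <- decompose_mol_node_vector(numeric(45))
  expect_length(zeros$problems, 6)            # every one-hot block unset
  expect_error(decompose_mol_node_vector(numeric(44)),
               class = "affipose_dimension_error")
})

test_that("round trip: decomposition recovers categorical attributes of every panel atom", {
  for (g in panel_mols()) {
    for (i in seq_len(nrow(g$atom_features))) {
      d <- decompose_mol_node_vector(g$atom_features[i, ])
      expect_length(d$problems, 0)
      a <- g$atoms[[i]]
      expect_equal(d$labels$atom_type,
                   if (a$element %in% affipose:::MOL_ATOM_TYPES) a$element else "other")
      expect_equal(d$labels$is_aromatic, if (a$is_aromatic) "yes" else "no")
      expect_equal(d$labels$chirality, a$chirality)
    }
  }
})

test_that("molecular graphs from SMILES have the expected topology", {
  eth <- mol_graph_from_structure("CC")
  expect_equal(nrow(eth$atom_features), 2)
  expect_equal(nrow(eth$edge_index), 2)       # one bond, both directions
  b <- eth$bonds[[1]]
  expect_equal(b$type, "single")
  expect_false(b$conjugated)
  expect_false(b$in_ring)
  benz <- mol_graph_from_structure("c1ccccc1")
  expect_equal(nrow(benz$atom_features), 6)
  expect_equal(nrow(benz$edge_index), 12)
  expect_true(all(vapply(benz$bonds, function(b) b$type, "") == "aromatic"))
  expect_true(all(vapply(benz$bonds, function(b) b$in_ring, TRUE)))
  expect_true(all(benz$atom_features[, 37] == 1))  # aromatic one-hot
})

test_that("file coordinates are centroid-centered before scaling", {
  sdf <- c("toy", "  test", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    3.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "  2  3  1  0  0  0  0",
           "M  END", "$$$$")
  f <- tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  g <- mol_graph_from_structure(f)
  expect_equal(g$coords[, 1], c(-1.5, 0, 1.5))
  expect_equal(g$coords[, 2], c(0, 0, 0))
  # scaled coordinates inside the feature vector
  expect_equal(g$atom_features[, 18], c(-0.15, 0, 0.15))
  # absolute placement retained for pose work
  expect_equal(pose_coords(g)[, 1], c(0, 1.5, 3))
})

test_that("geometric stereo perception matches reference CIP labels", {
  # labels verified against an independent cheminformatics toolkit
  chir <- function(smi) {
    g <- mol_graph_from_structure(smi)
    labs <- vapply(g$atoms, function(a) a$chirality, "")
    labs[labs != "other"]
  }
  expect_equal(unname(chir("F[C@H](Cl)Br")), "R")
  expect_equal(unname(chir("F[C@@H](Cl)Br")), "S")
  stereo <- function(smi) {
    g <- mol_graph_from_structure(smi)
    s <- vapply(g$bonds, function(b) b$stereo, "")
    s[s != "none"]
  }
  expect_equal(unname(stereo("C/C=C/C(=O)O")), "E")
  expect_equal(unname(stereo("C/C=C\\C")), "Z")
})

test_that("every molecule has exactly one atom-type slot per atom", {
  for (g in panel_mols()) {
    expect_equal(sum(g$atom_features[, 1:17]), nrow(g$atom_features))
  }
})

test_that("unparsable and coordinate-free inputs are rejected", {
  expect_error(mol_graph_from_structure("not_a_smiles(("),
               class = "affipose_error")
  expect_error(mol_graph_from_structure("CC", conformer_policy = "use_file_coords"),
               class = "affipose_invalid_input")
})

test_that("the JSON graph dump uses 0-based indices and round-trips content", {
  g <- mol_graph_from_structure("CCO")
  f <- tempfile(fileext = ".json")
  write_graph_json(g, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$kind, "molecule")
  expect_equal(min(j$edges), 0)
  expect_equal(max(j$edges), nrow(g$atom_features) - 1)
  expect_equal(dim(j$node_feats), dim(g$atom_features))
  expect_equal(j$atoms, g$atom_symbols)
})

test_that("SMILES files with ids are parsed", {
  f <- tempfile()
  writeLines(c("CC\tethane", "c1ccccc1"), f)
  df <- read_smiles_file(f)
  expect_equal(df$smiles, c("CC", "c1ccccc1"))
  expect_equal(df$id[1], "ethane")
})
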