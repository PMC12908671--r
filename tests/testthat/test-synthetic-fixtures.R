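test_that("the SMILES panel jointly covers every featurizer category", {
  mols <- panel_mols()
  atom_types <- unique(unlist(lapply(mols, function(g) {
    vapply(g$atoms, function(a)
      if (a$element %in% affipose:::MOL_ATOM_TYPES) a$element else "other", "")
  })))
  expect_setequal(atom_types, affipose:::MOL_ATOM_TYPES)   # all 17 slots
  bond_types <- unique(unlist(lapply(mols, function(g)
    vapply(g$bonds, function(b) b$type, ""))))
  expect_setequal(bond_types, c("single", "double", "triple", "aromatic"))
  stereo <- unlist(lapply(mols, function(g) vapply(g$bonds, function(b) b$stereo, "")))
  expect_true(all(c("E", "Z") %in% stereo))
  chir <- unlist(lapply(mols, function(g) vapply(g$atoms, function(a) a$chirality, "")))
  expect_true(all(c("R", "S") %in% chir))
  hyb <- unlist(lapply(mols, function(g) vapply(g$atoms, function(a) a$hybridization, "")))
  expect_true(all(c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other") %in% hyb))
  arom <- unlist(lapply(mols, function(g) vapply(g$atoms, function(a) a$is_aromatic, TRUE)))
  expect_true(any(arom) && !all(arom))
  degs <- unlist(lapply(mols, function(g) vapply(g$atoms, function(a) a$degree, 0L)))
  expect_true(all(c(0L, 4L, 5L, 6L) %in% degs))
  charges <- unlist(lapply(mols, function(g) vapply(g$atoms, function(a) a$formal_charge, 0)))
  expect_true(any(charges > 0) && any(charges < 0))
  # every panel graph passes the structural invariants
  for (g in mols) expect_silent(validate_mol_graph(g))
})

test_that("toy molecules are deterministic given the seed", {
  a <- make_toy_molecules(5, seed = 1)
  b <- make_toy_molecules(5, seed = 1)
  for (k in 1:5) expect_identical(a[[k]]$coords, b[[k]]$coords)
  # recycling beyond the panel keeps ids distinct
  many <- make_toy_molecules(30, seed = 1)
  expect_equal(length(unique(vapply(many, function(g) g$source_id, ""))), 30)
})

test_that("toy helices have ideal backbone dihedrals and a dense contact graph", {
  tp <- helix8()
  f <- tp$graph$residue_features
  expect_true(all(abs(f[2:7, 28] * 180 + 57) < 1))   # phi
  expect_true(all(abs(f[2:7, 29] * 180 + 47) < 1))   # psi
  ei <- tp$graph$edge_index
  for (i in 1:7) expect_true(any(ei[, 1] == i & ei[, 2] == i + 1))
  expect_equal(sort_edges(ei), unname(sort_edges(oracle_contact_pairs(tp$residues))))
  expect_error(make_toy_protein(3), class = "affipose_invalid_input")
})

test_that("a metal-bearing helix exercises the metal slot and X sequence code", {
  tm <- helix_metal()
  expect_true(any(tm$graph$residue_features[, 21] == 1))
  expect_match(tm$sequence, "X")
  enc <- encode_sequence(tm$sequence, N = 20)
  expect_equal(enc$true_length, nchar(tm$sequence))
  expect_equal(enc$codes[nchar(tm$sequence)], 20L)   # metal -> X -> last code
})

test_that("pose sets plant exact RMSD magnitudes", {
  mol <- panel_mols()[[4]]
  mags <- c(0, 3.5, 0.5, 1.9, 2.1)
  poses <- make_pose_set(mol, mags, seed = 9)
  for (k in seq_along(mags)) {
    expect_equal(pose_rmsd(pose_coords(mol), pose_coords(poses[[k]])),
                 mags[k], tolerance = 1e-9)
  }
  recs <- label_pose_set(mol, poses[3:5], helix8()$graph)
  expect_equal(vapply(recs[-1], function(r) r$near_native, TRUE),
               c(TRUE, TRUE, FALSE))
  expect_error(make_pose_set(mol, -1), class = "affipose_invalid_input")
})

test_that("planted labels separate signal from noise and stay in range", {
  spec <- fixture_spec(6, 2, 1, noise_sd = 0, seed = 3, n_res_base = 8)
  ds <- make_fixture_dataset(spec)
  aff <- vapply(ds$complexes, function(c) c$affinity, 0)
  expect_true(all(aff >= 5 - 1e-9 & aff <= 11 + 1e-9))
  # noise-free labels reproduce the documented formula through the rescale
  raw <- vapply(ds$complexes, function(cx) {
    nh <- nrow(cx$mol$coords)
    na <- sum(cx$mol$atom_features[, 37])
    cc <- affipose:::count_contacts6(cx$mol, cx$prot_residues,
                                     attr(cx$mol, "frame_shift"))
    nh + 2 * na + 0.1 * cc
  }, 0)
  rng <- range(raw)
  expect_equal(aff, 5 + 6 * (raw - rng[1]) / diff(rng), tolerance = 1e-9)
  # two seeds differ only in noise, not in the systematic part
  l1 <- plant_labels(ds$complexes, "contact_count", noise_sd = 0.2, seed = 1)
  l2 <- plant_labels(ds$complexes, "contact_count", noise_sd = 0.2, seed = 2)
  expect_identical(attr(l1, "systematic"), attr(l2, "systematic"))
  expect_false(isTRUE(all.equal(as.numeric(l1), as.numeric(l2))))
})

test_that("a linear model on the documented covariates recovers the planted signal", {
  spec <- fixture_spec(12, 3, 1, noise_sd = 0, seed = 5, n_res_base = 8)
  ds <- make_fixture_dataset(spec)
  df <- do.call(rbind, lapply(ds$complexes, function(cx) {
    data.frame(y = cx$affinity,
               nh = nrow(cx$mol$coords),
               na = sum(cx$mol$atom_features[, 37]),
               cc = affipose:::count_contacts6(cx$mol, cx$prot_residues,
                                               attr(cx$mol, "frame_shift")))
  }))
  fit <- lm(y ~ nh + na + cc, data = df)
  r2 <- 1 - sum(residuals(fit)^2) / sum((df$y - mean(df$y))^2)
  expect_gte(r2, 0.9)
})

test_that("cold splits respect entity disjointness and drop counts", {
  spec <- fixture_spec(10, 4, 1, seed = 2, n_res_base = 8)
  ds <- make_fixture_dataset(spec)
  recs <- ds$records
  mol_of <- vapply(recs, function(r) sub("\\|.*$", "", r$complex_id), "")
  prot_of <- vapply(recs, function(r) sub("^.*\\|", "", r$complex_id), "")
  df <- data.frame(mol_id = mol_of, prot_id = prot_of)
  sp <- make_cold_splits(df, "molecule", 0.2, seed = 1)
  expect_length(sp$test_molecules, 2)         # 10 molecules, fraction 0.2
  expect_length(intersect(df$mol_id[sp$train], df$mol_id[sp$test]), 0)
  expect_length(sp$dropped, 0)
  # all complexes of a held-out molecule land in test
  for (m in sp$test_molecules) {
    expect_true(all(which(df$mol_id == m) %in% sp$test))
  }
  pp <- make_cold_splits(df, "protein", 0.25, seed = 1)
  expect_length(intersect(df$prot_id[pp$train], df$prot_id[pp$test]), 0)
  for (seed in 1:20) {
    pr <- make_cold_splits(df, "pair", 0.25, seed = seed)
    expect_length(intersect(df$mol_id[pr$train], df$mol_id[pr$test]), 0)
    expect_length(intersect(df$prot_id[pr$train], df$prot_id[pr$test]), 0)
    # closed-form cross-pair count for the full molecule x protein cross
    n_tm <- length(pr$test_molecules); n_tp <- length(pr$test_proteins)
    n_m <- length(unique(df$mol_id)); n_p <- length(unique(df$prot_id))
    reps <- length(recs) / (n_m * n_p)        # records per (mol, prot) pair
    expect_equal(length(pr$dropped),
                 reps * ((n_m - n_tm) * n_tp + n_tm * (n_p - n_tp)))
    expect_equal(length(pr$train) + length(pr$test) + length(pr$dropped),
                 length(recs))
  }
  expect_error(make_cold_splits(df, "molecule", 0.01, seed = 1),
               class = "affipose_invalid_input")
})
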