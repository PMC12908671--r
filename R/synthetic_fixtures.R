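#' Deterministic synthetic fixtures
#'
#' A no-download test bed: toy molecules from a fixed SMILES panel (covering
#' every atom-type, bond-type, hybridization, charge, stereo and aromaticity
#' category of the molecular featurizer), idealized alpha-helical proteins
#' with plausible backbone geometry, pose sets with analytically known RMSD
#' labels (rigid unit-direction translations), affinity labels planted by a
#' documented linear rule over graph features, and the three cold-start split
#' constructions.
#'
#' @name synthetic_fixtures
NULL

#' The fixed SMILES panel backing [make_toy_molecules()]
#'
#' 5-30 heavy atoms per entry; jointly the panel exercises all 17 atom-type
#' slots (including the bare metals and the "other" catch-all), aromatic and
#' aliphatic rings, triple bonds, charges, hypervalent centers, E/Z double
#' bonds and R/S stereocenters.
#'
#' @return Named character vector of SMILES.
#' @export
fixture_smiles_panel <- function() {
  c(methane = "C",
    acetonitrile = "CC#N",
    phenol = "Oc1ccccc1",
    toluidine = "Cc1ccccc1N",
    r_halomethane = "F[C@H](Cl)Br",
    s_halomethane = "F[C@@H](Cl)Br",
    e_crotonic = "C/C=C/C(=O)O",
    z_butene = "C/C=C\\C",
    tetramethylammonium = "C[N+](C)(C)C",
    acetate = "CC(=O)[O-]",
    mesylate = "CS(=O)(=O)O",
    methyl_phosphate = "COP(=O)(O)O",
    phenylboronic = "OB(O)c1ccccc1",
    tetramethylsilane = "C[Si](C)(C)C",
    dimethylselenide = "C[Se]C",
    sulfur_hexafluoride = "FS(F)(F)(F)(F)F",
    phosphorus_pentachloride = "ClP(Cl)(Cl)(Cl)Cl",
    neopentane = "CC(C)(C)C",
    cyclohexane = "C1CCCCC1",
    ibuprofen_like = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    ethyl_iodide = "CCI",
    iron = "[Fe]",
    zinc = "[Zn]",
    copper = "[Cu]",
    manganese = "[Mn]",
    molybdenum = "[Mo]")
}

.fixture_env <- new.env(parent = emptyenv())

#' Fixture generator specification
#'
#' @param n_molecules,n_proteins,poses_per_complex Counts (>= 1);
#'   `poses_per_complex` counts decoys (the native pose is always included).
#'   Default 10 decoys per complex, emulating re-docking decoy sets.
#' @param noise_sd Gaussian noise on planted affinity labels (default 0.1).
#' @param seed Integer seed fixing every downstream draw.
#' @param planted_rule "contact_count" (default) or "atom_type_linear".
#' @param n_res_base Protein sizes: the k-th protein has
#'   `n_res_base + 2 * k` residues (default base 12, i.e. 14-20 residues for
#'   four proteins).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 10L, n_proteins = 4L,
                         poses_per_complex = 10L, noise_sd = 0.1,
                         seed = 1L,
                         planted_rule = c("contact_count", "atom_type_linear"),
                         n_res_base = 12L) {
  if (n_molecules < 1 || n_proteins < 1 || poses_per_complex < 1) {
    ap_abort("fixture counts must be >= 1", "affipose_invalid_input")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_proteins = as.integer(n_proteins),
                 poses_per_complex = as.integer(poses_per_complex),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 planted_rule = match.arg(planted_rule),
                 n_res_base = as.integer(n_res_base)),
            class = "fixture_spec")
}

#' Toy molecules from the fixed panel
#'
#' 3D coordinates come from the deterministic seeded RDKit embedding, so the
#' same seed always yields identical coordinate matrices. Requests beyond the
#' panel size recycle panel entries under fresh identifiers.
#'
#' @param n Number of molecules.
#' @param seed Integer seed for the embedding.
#' @return List of `mol_graph`s.
#' @export
make_toy_molecules <- function(n = length(fixture_smiles_panel()), seed = 1L) {
  panel <- fixture_smiles_panel()
  key <- sprintf("panel_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    sdf <- embed_smiles_batch(unname(panel), seed = seed)
    .fixture_env[[key]] <- lapply(seq_along(panel), function(i) {
      mol_graph_from_sdf_text(sdf[[i]], source_id = names(panel)[i])
    })
  }
  base <- .fixture_env[[key]]
  lapply(seq_len(n), function(i) {
    g <- base[[(i - 1L) %% length(base) + 1L]]
    g$source_id <- sprintf("%s_%02d", g$source_id, i)
    g
  })
}

AA_1TO3 <- stats::setNames(names(AA_3TO1), AA_3TO1)

# NeRF: place atom D given A-B-C, bond length r(C-D), bond angle theta
# (B-C-D) and torsion phi (A-B-C-D), angles in degrees.
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / vec_norm(bc)
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vec_norm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Idealized alpha-helical toy protein
#'
#' Backbone built residue by residue from ideal internal coordinates
#' (phi -57, psi -47, omega 180 degrees; standard bond lengths/angles), with
#' CB/gamma atoms at chi1 = -60 degrees for residues that carry them, so
#' every dihedral feature is exercised. The sequence is sampled over all 20
#' letters; with `include_metal` a zinc ion is appended 6 Angstrom off the
#' middle residue ("X" in the returned sequence, "metal" node in the graph).
#'
#' @param n_res Number of residues (4 to 200).
#' @param seed Integer seed.
#' @param include_metal Logical; default draws it from the seed.
#' @return List with `graph` (a `prot_graph`), `sequence` and `residues`.
#' @export
make_toy_protein <- function(n_res = 16L, seed = 1L, include_metal = NULL) {
  if (n_res < 4 || n_res > 200) {
    ap_abort("n_res must be in [4, 200]", "affipose_invalid_input")
  }
  set.seed(seed)
  letters20 <- unname(AA_3TO1)
  seq1 <- sample(letters20, n_res, replace = TRUE)
  if (is.null(include_metal)) include_metal <- stats::runif(1) < 0.5
  phi <- -57; psi <- -47; omega <- 180
  res_atoms <- vector("list", n_res)
  # residue 1 backbone seeded in the xy-plane
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(-cos(111 * pi / 180), sin(111 * pi / 180), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      prevv <- res_atoms[[i - 1]]
      N <- nerf_place(prevv$N, prevv$CA, prevv$C, 1.329, 116.2, psi)
      CA <- nerf_place(prevv$CA, prevv$C, N, 1.458, 121.7, omega)
      C <- nerf_place(prevv$C, N, CA, 1.525, 111.0, phi)
    }
    O <- nerf_place(N, CA, C, 1.231, 120.8, psi - 180)
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (seq1[i] != "G") {
      atoms$CB <- nerf_place(N, C, CA, 1.530, 110.1, 122.6)
      if (seq1[i] != "A") {
        atoms$CG <- nerf_place(N, CA, atoms$CB, 1.520, 114.0, -60)
      }
    }
    res_atoms[[i]] <- atoms
  }
  residues <- lapply(seq_len(n_res), function(i) {
    list(name = unname(AA_1TO3[seq1[i]]),
         atom_names = names(res_atoms[[i]]),
         coords = do.call(rbind, res_atoms[[i]]),
         is_metal = FALSE)
  })
  if (include_metal) {
    mid <- res_atoms[[ceiling(n_res / 2)]]$CA
    residues[[n_res + 1]] <- list(name = "ZN", atom_names = "ZN",
                                  coords = matrix(mid + c(0, 0, 6), 1),
                                  is_metal = TRUE)
  }
  g <- prot_graph_from_residues(residues,
                                source_id = sprintf("helix%02d_s%d", n_res, seed))
  list(graph = g, sequence = g$sequence, residues = residues)
}

#' Pose set with exactly planted RMSD labels
#'
#' Each pose is the native pose displaced rigidly along a seeded random unit
#' direction, scaled so the coordinate RMSD to the native equals the
#' requested magnitude exactly (every atom moves by the same vector, so RMSD
#' equals the displacement length). Poses keep the centroid-centered `coords`
#' of the featurization contract; the rigid placement is carried in the
#' `frame_shift` attribute read by [pose_coords()].
#'
#' @param mol Native `mol_graph`.
#' @param magnitudes Numeric vector of requested RMSDs (Angstrom, >= 0).
#' @param seed Integer seed for the directions.
#' @return List of `mol_graph` poses.
#' @export
make_pose_set <- function(mol, magnitudes, seed = 1L) {
  if (any(magnitudes < 0)) {
    ap_abort("pose magnitudes must be >= 0", "affipose_invalid_input")
  }
  set.seed(seed)
  base_shift <- attr(mol, "frame_shift") %||% c(0, 0, 0)
  lapply(seq_along(magnitudes), function(k) {
    u <- stats::rnorm(3)
    u <- u / vec_norm(u)
    pose <- mol
    pose$source_id <- sprintf("%s_pose%02d", mol$source_id, k)
    attr(pose, "frame_shift") <- base_shift + magnitudes[k] * u
    pose
  })
}

#' Coordinates of a pose in the shared receptor frame
#' @param mol A `mol_graph` (optionally carrying a `frame_shift`).
#' @return \[n x 3\] coordinate matrix in Angstrom.
#' @export
pose_coords <- function(mol) native_frame_coords(mol)

# number of (atom, residue) pairs with min atomic distance < 6 A
count_contacts6 <- function(mol, prot_residues, shift) {
  xyz <- sweep(mol$coords, 2, shift, `+`)
  total <- 0L
  for (res in prot_residues) {
    d2 <- outer(rowSums(xyz^2), rowSums(res$coords^2), "+") -
      2 * tcrossprod(xyz, res$coords)
    total <- total + sum(apply(d2, 1, min) < 36)
  }
  total
}

planted_raw_score <- function(mol, prot_residues, shift, rule) {
  n_heavy <- nrow(mol$coords)
  arom_block <- mol$atom_features[, 36:37, drop = FALSE]  # is-aromatic one-hot
  n_arom <- sum(arom_block[, 2])
  if (rule == "contact_count") {
    # coefficients chosen so the molecule-borne covariates carry most of the
    # variance and the geometric contact term is a minor modifier
    n_heavy + 2 * n_arom + 0.1 * count_contacts6(mol, prot_residues, shift)
  } else {
    n_n <- sum(mol$atom_symbols == "N"); n_o <- sum(mol$atom_symbols == "O")
    n_heavy + 3 * n_n + 2 * n_o
  }
}

#' Plant affinity labels on complexes
#'
#' The systematic part is a documented linear score over graph features
#' ("contact_count" rule: heavy-atom count + 2 x aromatic-atom count + 0.1 x
#' count of atom-residue pairs within 6 Angstrom of the native placement),
#' affinely rescaled across the dataset to the pKd-like range \[5, 11\], plus
#' Gaussian noise. Noise and signal are separated: two seeds differ only in
#' the noise draws.
#'
#' @param complexes List of lists with `mol` (native pose, `frame_shift`
#'   set), `prot_residues`, `complex_id`.
#' @param rule "contact_count" or "atom_type_linear".
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed (noise only).
#' @return Numeric affinity vector aligned with `complexes`; attribute
#'   `systematic` holds the noise-free labels.
#' @export
plant_labels <- function(complexes, rule = "contact_count", noise_sd = 0.1,
                         seed = 1L) {
  raw <- vapply(complexes, function(cx) {
    planted_raw_score(cx$mol, cx$prot_residues,
                      attr(cx$mol, "frame_shift") %||% c(0, 0, 0), rule)
  }, 0)
  rng <- range(raw)
  sys <- if (diff(rng) < 1e-12) rep(8, length(raw)) else {
    5 + 6 * (raw - rng[1]) / diff(rng)
  }
  set.seed(seed)
  out <- sys + stats::rnorm(length(sys), 0, noise_sd)
  attr(out, "systematic") <- sys
  attr(out, "raw") <- raw
  out
}

#' Full synthetic complex dataset
#'
#' Crosses `n_molecules` toy molecules with `n_proteins` toy helices. Each
#' complex places the molecule centroid 3.5-6 Angstrom off a seeded surface
#' residue, plants an affinity label from the native placement, and attaches
#' `poses_per_complex` decoys with RMSD magnitudes drawn from
#' U(0.25, 5) Angstrom (straddling the 2 Angstrom near-native threshold).
#'
#' @param spec A [fixture_spec()].
#' @return List with `records` (flat list of `complex_record`s over all
#'   poses), `complexes`, `molecules`, `proteins`.
#' @export
make_fixture_dataset <- function(spec = fixture_spec()) {
  mols <- make_toy_molecules(spec$n_molecules, seed = spec$seed)
  prots <- lapply(seq_len(spec$n_proteins), function(k) {
    make_toy_protein(n_res = spec$n_res_base + 2L * k,
                     seed = spec$seed * 1000L + k,
                     include_metal = k %% 2L == 0L)
  })
  set.seed(spec$seed + 7L)
  complexes <- list()
  for (pi_ in seq_len(spec$n_proteins)) {
    for (mi in seq_len(spec$n_molecules)) {
      prot <- prots[[pi_]]
      anchor <- prot$residues[[sample.int(length(prot$residues), 1)]]
      dirn <- stats::rnorm(3); dirn <- dirn / vec_norm(dirn)
      shift <- colMeans(anchor$coords) + stats::runif(1, 3.5, 6) * dirn
      mol <- mols[[mi]]
      attr(mol, "frame_shift") <- shift
      complexes[[length(complexes) + 1]] <-
        list(mol = mol, prot = prot$graph, prot_residues = prot$residues,
             complex_id = sprintf("%s|%s", mol$source_id, prot$graph$source_id),
             mol_id = mol$source_id, prot_id = prot$graph$source_id)
    }
  }
  aff <- plant_labels(complexes, spec$planted_rule, spec$noise_sd,
                      seed = spec$seed + 11L)
  records <- list()
  for (k in seq_along(complexes)) {
    cx <- complexes[[k]]
    mags <- stats::runif(spec$poses_per_complex, 0.25, 5)
    decoys <- make_pose_set(cx$mol, mags, seed = spec$seed * 100L + k)
    rec <- label_pose_set(cx$mol, decoys, cx$prot, affinity = aff[k],
                          complex_id = cx$complex_id,
                          mol_offset = attr(cx$mol, "frame_shift"))
    records <- c(records, rec)
    complexes[[k]]$affinity <- aff[k]
  }
  list(records = records, complexes = complexes,
       molecules = mols, proteins = prots)
}

#' Cold-start train/test splits
#'
#' "molecule" mode holds out whole molecules, "protein" whole proteins,
#' "pair" both (records pairing a train molecule with a test protein, or vice
#' versa, are dropped).
#'
#' @param records List of records (each with `mol_id`/`prot_id`, or
#'   `complex_record`s whose graphs carry source ids) or a data.frame with
#'   `mol_id`, `prot_id` columns.
#' @param mode "molecule", "protein" or "pair".
#' @param test_fraction Fraction of distinct entities held out (per entity
#'   type).
#' @param seed Integer seed.
#' @return List with `train`, `test` (record indices), `dropped` (pair mode),
#'   `test_molecules`, `test_proteins`.
#' @export
make_cold_splits <- function(records, mode = c("molecule", "protein", "pair"),
                             test_fraction = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  if (is.data.frame(records)) {
    mol_ids <- records$mol_id; prot_ids <- records$prot_id
  } else {
    mol_ids <- vapply(records, function(r) {
      r$mol_id %||% sub("_pose[0-9]+$", "", r$mol$source_id)
    }, "")
    prot_ids <- vapply(records, function(r) r$prot_id %||% r$prot$source_id, "")
  }
  mols <- unique(mol_ids); prots <- unique(prot_ids)
  n_tm <- round(test_fraction * length(mols))
  n_tp <- round(test_fraction * length(prots))
  if ((mode != "protein" && (n_tm < 1 || n_tm >= length(mols))) ||
      (mode != "molecule" && (n_tp < 1 || n_tp >= length(prots)))) {
    ap_abort("test fraction infeasible for the number of distinct entities",
             "affipose_invalid_input")
  }
  set.seed(seed)
  test_mols <- if (mode != "protein") sample(mols, n_tm) else character()
  test_prots <- if (mode != "molecule") sample(prots, n_tp) else character()
  in_tm <- mol_ids %in% test_mols
  in_tp <- prot_ids %in% test_prots
  if (mode == "molecule") {
    test <- which(in_tm); train <- which(!in_tm); dropped <- integer()
  } else if (mode == "protein") {
    test <- which(in_tp); train <- which(!in_tp); dropped <- integer()
  } else {
    test <- which(in_tm & in_tp)
    train <- which(!in_tm & !in_tp)
    dropped <- which(xor(in_tm, in_tp))
  }
  list(train = train, test = test, dropped = dropped,
       test_molecules = test_mols, test_proteins = test_prots)
}
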