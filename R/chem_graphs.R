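#' Molecular graph featurization
#'
#' Small molecules are represented as directed graphs \code{G_M = (N_M, E_M)}
#' over heavy atoms: each bond is stored twice (once per direction) so the
#' attention layer can treat edges as ordered pairs. Node feature vectors have
#' width 45 and edge feature vectors width 12; the block layout is fixed and
#' documented in [mol_node_blocks()] / [mol_edge_blocks()].
#'
#' @name chem_graphs
NULL

MOL_ATOM_TYPES <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B",
                    "Si", "Fe", "Zn", "Cu", "Mn", "Mo", "other")
MOL_DEGREES <- c("0", "1", "2", "3", "4", "5", "other")
MOL_HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
MOL_AROMATIC <- c("no", "yes")
MOL_NUM_H <- c("0", "1", "2", "3", "other")
MOL_CHIRALITY <- c("R", "S", "other")
MOL_BOND_TYPES <- c("single", "double", "triple", "aromatic")
MOL_BOND_BOOL <- c("no", "yes")
MOL_BOND_STEREO <- c("none", "any", "Z", "E")

#' Block layout of the 45-wide molecular node feature vector
#'
#' Blocks in order: atom-type one-hot (17), scaled x/y/z coordinates (3),
#' degree one-hot (7), formal charge (1), radical electrons (1),
#' hybridization one-hot (6), is-aromatic one-hot (2), hydrogen-count one-hot
#' (5), chirality one-hot (3). Coordinates are centroid-centered and divided
#' by the package-wide `distance_scale` of 10.
#'
#' @return Named list mapping block name to its category labels (or width for
#'   scalar blocks).
#' @export
mol_node_blocks <- function() {
  list(atom_type = MOL_ATOM_TYPES,
       position = 3L,
       degree = MOL_DEGREES,
       formal_charge = 1L,
       radical_electrons = 1L,
       hybridization = MOL_HYBRIDIZATIONS,
       is_aromatic = MOL_AROMATIC,
       num_h = MOL_NUM_H,
       chirality = MOL_CHIRALITY)
}

#' Block layout of the 12-wide molecular edge feature vector
#'
#' Bond-type one-hot (4), conjugated one-hot (2), in-ring one-hot (2),
#' stereo one-hot (4).
#'
#' @return Named list of block labels.
#' @export
mol_edge_blocks <- function() {
  list(bond_type = MOL_BOND_TYPES,
       conjugated = MOL_BOND_BOOL,
       in_ring = MOL_BOND_BOOL,
       stereo = MOL_BOND_STEREO)
}

block_width <- function(b) if (is.numeric(b)) as.integer(b) else length(b)

#' @rdname mol_node_blocks
#' @export
mol_node_width <- function() sum(vapply(mol_node_blocks(), block_width, 1L))

#' @rdname mol_edge_blocks
#' @export
mol_edge_width <- function() sum(vapply(mol_edge_blocks(), block_width, 1L))

#' Featurize one atom into the 45-wide node vector
#'
#' @param atom A record (named list) with fields `element`, `degree`,
#'   `formal_charge`, `radical_electrons`, `hybridization` (one of
#'   sp/sp2/sp3/sp3d/sp3d2; anything else maps to "other"), `is_aromatic`
#'   (logical), `num_h`, `chirality` ("R", "S" or anything else -> "other").
#' @param coord Length-3 numeric, centroid-centered coordinates in Angstrom.
#' @return Numeric vector of length 45.
#' @export
featurize_atom <- function(atom, coord = c(0, 0, 0)) {
  if (is.null(atom$element) || !nzchar(atom$element)) {
    ap_abort("atom record has empty element", "affipose_invalid_input")
  }
  if (length(coord) != 3L || !all(is.finite(coord))) {
    ap_abort("atom coordinate must be a finite 3-vector", "affipose_invalid_input")
  }
  deg <- as.character(atom$degree %||% 0L)
  hyb <- as.character(atom$hybridization %||% "other")
  if (!hyb %in% MOL_HYBRIDIZATIONS) hyb <- "other"
  nh <- as.character(atom$num_h %||% 0L)
  chir <- as.character(atom$chirality %||% "other")
  if (!chir %in% MOL_CHIRALITY) chir <- "other"
  c(one_hot(atom$element, MOL_ATOM_TYPES, other = "other"),
    coord / DISTANCE_SCALE,
    one_hot(deg, MOL_DEGREES, other = "other"),
    as.numeric(atom$formal_charge %||% 0),
    as.numeric(atom$radical_electrons %||% 0),
    one_hot(hyb, MOL_HYBRIDIZATIONS, other = "other"),
    one_hot(if (isTRUE(atom$is_aromatic)) "yes" else "no", MOL_AROMATIC),
    one_hot(nh, MOL_NUM_H, other = "other"),
    one_hot(chir, MOL_CHIRALITY))
}

#' Featurize one bond into the 12-wide edge vector
#'
#' @param bond A record with fields `type` (single/double/triple/aromatic),
#'   `conjugated` (logical), `in_ring` (logical), `stereo` (none/any/Z/E).
#' @return Numeric vector of length 12.
#' @export
featurize_bond <- function(bond) {
  type <- tolower(as.character(bond$type %||% ""))
  if (!type %in% MOL_BOND_TYPES) {
    ap_abort(sprintf("bond type '%s' not one of single/double/triple/aromatic", type),
             "affipose_invalid_input")
  }
  stereo <- as.character(bond$stereo %||% "none")
  stereo <- sub("^Stereo", "", stereo)
  stereo <- switch(tolower(stereo), none = "none", any = "any",
                   z = "Z", e = "E",
                   ap_abort(sprintf("bond stereo '%s' unknown", stereo),
                            "affipose_invalid_input"))
  c(one_hot(type, MOL_BOND_TYPES),
    one_hot(if (isTRUE(bond$conjugated)) "yes" else "no", MOL_BOND_BOOL),
    one_hot(if (isTRUE(bond$in_ring)) "yes" else "no", MOL_BOND_BOOL),
    one_hot(stereo, MOL_BOND_STEREO))
}

#' Decompose a 45-wide molecular node vector into its named blocks
#'
#' Inverse of the [featurize_atom()] layout; used for round-trip checks and
#' debugging. Each one-hot block is decoded to its category label; a block
#' that is not exactly one-hot is reported as a validation problem.
#'
#' @param v Numeric vector of length 45.
#' @return List with `blocks` (raw sub-vectors), `labels` (decoded categories,
#'   `NA` where invalid), `scalars` (position, formal charge, radicals) and
#'   `problems` (character vector, empty when every one-hot block is valid).
#' @export
decompose_mol_node_vector <- function(v) {
  if (length(v) != mol_node_width()) {
    ap_abort(sprintf("expected vector of length %d, got %d",
                     mol_node_width(), length(v)),
             "affipose_dimension_error")
  }
  layout <- mol_node_blocks()
  blocks <- list(); labels <- list(); problems <- character()
  pos <- 1L
  for (nm in names(layout)) {
    w <- block_width(layout[[nm]])
    blk <- v[pos:(pos + w - 1L)]
    blocks[[nm]] <- blk
    if (!is.numeric(layout[[nm]])) {
      dec <- decode_one_hot(blk, layout[[nm]])
      labels[[nm]] <- dec$label
      if (!dec$ok) problems <- c(problems, sprintf("block '%s': no category set", nm))
    }
    pos <- pos + w
  }
  list(blocks = blocks,
       labels = labels,
       scalars = list(position = blocks$position * DISTANCE_SCALE,
                      formal_charge = blocks$formal_charge,
                      radical_electrons = blocks$radical_electrons),
       problems = problems)
}

new_mol_graph <- function(atom_features, edge_index, edge_features, coords,
                          atom_symbols, source_id, atoms = NULL, bonds = NULL) {
  g <- structure(list(atom_features = atom_features,
                      edge_index = edge_index,
                      edge_features = edge_features,
                      coords = coords,
                      atom_symbols = atom_symbols,
                      source_id = source_id,
                      atoms = atoms,
                      bonds = bonds),
                 class = "mol_graph")
  validate_mol_graph(g)
  g
}

#' Validate the invariants of a molecular graph
#'
#' @param g A `mol_graph`.
#' @return The graph, invisibly; aborts on violation.
#' @export
validate_mol_graph <- function(g) {
  n <- nrow(g$atom_features)
  if (n < 1L) ap_abort("molecule must have at least one atom", "affipose_invalid_input")
  if (ncol(g$atom_features) != mol_node_width())
    ap_abort("atom_features width != 45", "affipose_dimension_error")
  m <- nrow(g$edge_index)
  if (m > 0L) {
    if (ncol(g$edge_features) != mol_edge_width())
      ap_abort("edge_features width != 12", "affipose_dimension_error")
    if (any(g$edge_index < 1L) || any(g$edge_index > n))
      ap_abort("edge_index out of range", "affipose_invalid_input")
    key <- paste(g$edge_index[, 1], g$edge_index[, 2])
    rev_key <- paste(g$edge_index[, 2], g$edge_index[, 1])
    if (!setequal(key, rev_key))
      ap_abort("edge_index is not symmetric", "affipose_invalid_input")
  }
  if (!all(is.finite(g$coords))) ap_abort("non-finite coordinates", "affipose_invalid_input")
  invisible(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d atoms, %d directed edges>\n",
              x$source_id, nrow(x$atom_features), nrow(x$edge_index)))
  invisible(x)
}

#' Build a molecular graph from SMILES or a structure file
#'
#' Accepts a SMILES string, an SDF/MOL file, or a PDB file (HETATM ligand
#' records; bonds perceived with Open Babel). Hydrogens are folded into the
#' hydrogen-count feature; the graph is over heavy atoms only. Coordinates are
#' centered at the heavy-atom centroid.
#'
#' For `conformer_policy = "generate_3d"`, 3D coordinates are produced by the
#' RDKit ETKDG embedding run through the `python` interpreter on the PATH with
#' a fixed random seed, so repeated calls give identical conformers.
#'
#' @param input SMILES string or path to an .sdf/.mol/.pdb file.
#' @param conformer_policy "use_file_coords" (default for files) or
#'   "generate_3d" (default for SMILES).
#' @param source_id Identifier stored on the graph; defaults to the input.
#' @param seed Integer seed for conformer generation.
#' @return A `mol_graph`.
#' @export
mol_graph_from_structure <- function(input,
                                     conformer_policy = NULL,
                                     source_id = NULL,
                                     seed = 1L) {
  is_file <- file.exists(input) &&
    grepl("\\.(sdf|mol|pdb)$", input, ignore.case = TRUE)
  if (is.null(conformer_policy)) {
    conformer_policy <- if (is_file) "use_file_coords" else "generate_3d"
  }
  conformer_policy <- match.arg(conformer_policy, c("use_file_coords", "generate_3d"))
  if (!is_file && conformer_policy == "use_file_coords") {
    ap_abort("SMILES input carries no coordinates; use conformer_policy='generate_3d'",
             "affipose_invalid_input")
  }
  if (is_file) {
    sdf_lines <- if (grepl("\\.pdb$", input, ignore.case = TRUE)) {
      pdb_ligand_to_sdf(input)
    } else {
      readLines(input, warn = FALSE)
    }
  } else {
    sdf_lines <- embed_smiles_batch(input, seed = seed)[[1]]
  }
  g <- mol_graph_from_sdf_text(sdf_lines, source_id = source_id %||% input)
  g
}

# Convert PDB ligand records to SDF text via openbabel (bond perception).
pdb_ligand_to_sdf <- function(path) {
  out <- tempfile(fileext = ".sdf")
  status <- suppressWarnings(system2("obabel", c(shQuote(path), "-osdf",
                                                 "-O", shQuote(out)),
                                     stdout = FALSE, stderr = FALSE))
  if (!file.exists(out) || file.size(out) == 0) {
    ap_abort(sprintf("could not parse ligand records from '%s'", path),
             "affipose_parse_error", record = path)
  }
  readLines(out, warn = FALSE)
}

# ---- RDKit-backed deterministic 3D embedding -------------------------------

#' Deterministic 3D embedding of SMILES strings
#'
#' Embeds each SMILES with RDKit's ETKDG distance-geometry algorithm (fixed
#' random seed, hydrogens added for the embedding and kept in the output) via
#' the `python` interpreter. One batched subprocess handles all inputs.
#'
#' @param smiles Character vector of SMILES.
#' @param seed Integer random seed for the embedding.
#' @return List of character vectors, each the SDF (V2000) text of one input.
#' @export
embed_smiles_batch <- function(smiles, seed = 1L) {
  script <- c(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem import AllChem",
    "inp = json.load(sys.stdin)",
    "out = []",
    "for smi in inp['smiles']:",
    "    m = Chem.MolFromSmiles(smi)",
    "    if m is None:",
    "        out.append(None); continue",
    "    m = Chem.AddHs(m)",
    "    p = AllChem.ETKDGv3()",
    "    p.randomSeed = int(inp['seed'])",
    "    ok = AllChem.EmbedMolecule(m, p)",
    "    if ok != 0 and m.GetNumAtoms() == 1:",
    "        conf = Chem.Conformer(1); conf.SetAtomPosition(0, (0.0, 0.0, 0.0))",
    "        m.AddConformer(conf); ok = 0",
    "    if ok != 0:",
    "        out.append(None); continue",
    "    out.append(Chem.MolToMolBlock(m, kekulize=True))",
    "print(json.dumps(out))")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  payload <- jsonlite::toJSON(list(smiles = as.list(smiles), seed = seed),
                              auto_unbox = TRUE)
  res <- suppressWarnings(system2("python", shQuote(sf), input = as.character(payload),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || length(res) == 0L) {
    ap_abort("RDKit embedding subprocess failed (is python+rdkit on the PATH?)",
             "affipose_provider_unavailable")
  }
  blocks <- jsonlite::fromJSON(res[length(res)], simplifyVector = FALSE)
  lapply(seq_along(blocks), function(i) {
    if (is.null(blocks[[i]])) {
      ap_abort(sprintf("could not parse or embed SMILES '%s'", smiles[i]),
               if (is.null(tryCatch(blocks[[i]], error = function(e) NULL)))
                 "affipose_parse_error" else "affipose_embedding_failure",
               record = smiles[i])
    }
    strsplit(blocks[[i]], "\n", fixed = TRUE)[[1]]
  })
}

# ---- SDF perception --------------------------------------------------------

ELEMENT_VALENCE_ELECTRONS <- c(C = 4, N = 5, O = 6, F = 7, P = 5, S = 6,
                               Cl = 7, Br = 7, I = 7, B = 3, Si = 4, Se = 6)
ELEMENT_DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                             Cl = 1, Br = 1, I = 1, B = 3, Si = 4, Se = 2)
MDL_CHARGE_CODE <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)

parse_sdf_counts <- function(lines) {
  cl <- lines[4]
  list(n_atoms = as.integer(substr(cl, 1, 3)),
       n_bonds = as.integer(substr(cl, 4, 6)))
}

# Minimal structured view of one V2000 molfile: atoms (element, xyz, charge,
# radical), bonds (a1, a2, order). Property-block M CHG / M RAD override the
# legacy atom-block codes, per the MDL spec.
parse_molfile <- function(lines) {
  cn <- parse_sdf_counts(lines)
  if (is.na(cn$n_atoms) || cn$n_atoms < 1) {
    ap_abort("unparsable molfile (bad counts line)", "affipose_parse_error")
  }
  at <- lines[5:(4 + cn$n_atoms)]
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  elem <- trimws(substr(at, 32, 34))
  ccode <- suppressWarnings(as.integer(trimws(substr(at, 37, 39))))
  charge <- ifelse(is.na(ccode) | ccode == 0, 0,
                   MDL_CHARGE_CODE[as.character(ccode)])
  charge[is.na(charge)] <- 0
  radical <- integer(cn$n_atoms)
  bonds <- NULL
  if (cn$n_bonds > 0) {
    bl <- lines[(5 + cn$n_atoms):(4 + cn$n_atoms + cn$n_bonds)]
    bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                        a2 = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  for (ln in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    kind <- substr(ln, 4, 6)
    nn <- as.integer(substr(ln, 7, 9))
    for (k in seq_len(nn)) {
      off <- 10 + (k - 1) * 8
      ai <- as.integer(substr(ln, off, off + 3))
      vv <- as.integer(substr(ln, off + 4, off + 7))
      if (kind == "CHG") charge[ai] <- vv
      if (kind == "RAD") radical[ai] <- c(2, 1, 2)[vv]  # singlet/doublet/triplet -> unpaired e-
    }
  }
  list(element = elem, coords = cbind(x, y, z), charge = as.numeric(charge),
       radical = radical, bonds = bonds)
}

# Aromatic ring perception: SSSR-free heuristic on the kekulized graph.
# A ring (simple cycle of length 5-7 found on the bond graph) is aromatic when
# every ring bond alternates double/single appropriately; we accept a ring as
# aromatic iff every ring atom carries at least one double bond inside the
# ring, or is O/S/N contributing a lone pair (5-rings). Covers the benzene,
# pyridine, furan/thiophene/pyrrole chemistry exercised by the fixtures.
perceive_aromatic <- function(mol) {
  n <- length(mol$element)
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(mol$bonds))
  if (nrow(mol$bonds) == 0) return(list(atom = arom_atom, bond = arom_bond))
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- rbind(adj[[a1]], c(a2, b))
    adj[[a2]] <- rbind(adj[[a2]], c(a1, b))
  }
  rings <- find_rings(adj, n, max_size = 7L)
  for (ring in rings) {
    atoms <- ring$atoms; bonds <- ring$bonds
    if (length(atoms) < 5 || length(atoms) > 7) next
    ok <- TRUE
    for (a in atoms) {
      in_ring_orders <- mol$bonds$order[bonds]
      my_bonds <- bonds[mol$bonds$a1[bonds] == a | mol$bonds$a2[bonds] == a]
      has_double <- any(mol$bonds$order[my_bonds] == 2)
      lone_pair_donor <- mol$element[a] %in% c("O", "S") ||
        (mol$element[a] == "N" && !any(mol$bonds$order[my_bonds] == 2))
      if (!has_double && !lone_pair_donor) { ok <- FALSE; break }
    }
    # require pi count roughly alternating: at least floor(size/2) double bonds
    # or one lone-pair donor replacing one double bond
    nd <- sum(mol$bonds$order[bonds] == 2)
    donors <- sum(mol$element[atoms] %in% c("O", "S") |
                    (mol$element[atoms] == "N" & !vapply(atoms, function(a) {
                      my_bonds <- bonds[mol$bonds$a1[bonds] == a | mol$bonds$a2[bonds] == a]
                      any(mol$bonds$order[my_bonds] == 2)
                    }, TRUE)))
    if (ok && (2 * nd + 2 * donors >= length(atoms))) {
      arom_atom[atoms] <- TRUE
      arom_bond[bonds] <- TRUE
    }
  }
  list(atom = arom_atom, bond = arom_bond)
}

# Enumerate simple cycles up to max_size via DFS from each bond (small
# molecules only; fixture-scale graphs have < 40 atoms).
find_rings <- function(adj, n, max_size = 7L) {
  rings <- list()
  seen <- character()
  walk <- function(path, path_bonds, start) {
    a <- path[length(path)]
    nb <- adj[[a]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]; bid <- nb[r, 2]
      if (length(path_bonds) > 0 && bid == path_bonds[length(path_bonds)]) next
      if (nxt == start && length(path) >= 3) {
        key <- paste(sort(c(path_bonds, bid)), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- list(atoms = path,
                                              bonds = c(path_bonds, bid))
        }
      } else if (!nxt %in% path && length(path) < max_size) {
        walk(c(path, nxt), c(path_bonds, bid), start)
      }
    }
  }
  for (a in seq_len(n)) walk(a, integer(), a)
  rings
}

# Is each bond in a ring? A bond is in a ring iff it is not a bridge.
bonds_in_ring <- function(bonds, n) {
  m <- nrow(bonds)
  if (m == 0) return(logical())
  in_ring <- logical(m)
  reachable <- function(from, to, skip) {
    seen <- logical(n); stack <- from; seen[from] <- TRUE
    while (length(stack)) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (a == to) return(TRUE)
      for (b in seq_len(m)) {
        if (b == skip) next
        nxt <- if (bonds$a1[b] == a) bonds$a2[b] else if (bonds$a2[b] == a) bonds$a1[b] else next
        if (!seen[nxt]) { seen[nxt] <- TRUE; stack <- c(stack, nxt) }
      }
    }
    FALSE
  }
  for (b in seq_len(m)) in_ring[b] <- reachable(bonds$a1[b], bonds$a2[b], b)
  in_ring
}

# CIP-like branch priority: breadth-first spheres of atomic numbers
# (implicit hydrogens included as Z=1 leaves). Returns a comparable key
# string per branch; ties mean "cannot rank".
ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                    S = 16, Cl = 17, Fe = 26, Cu = 29, Zn = 30, Mn = 25,
                    Se = 34, Br = 35, Mo = 42, I = 53)

branch_signature <- function(start, center, adj, element, nh, depth = 6L) {
  z <- function(e) ATOMIC_NUMBERS[e] %||% 0
  zn <- ATOMIC_NUMBERS[element]; zn[is.na(zn)] <- 0
  frontier <- list(list(atom = start, from = center))
  spheres <- character()
  for (d in seq_len(depth)) {
    zs <- integer()
    nxt <- list()
    for (f in frontier) {
      zs <- c(zs, zn[f$atom], rep(1L, nh[f$atom]))
      nb <- adj[[f$atom]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          if (nb[r, 1] != f$from) nxt[[length(nxt) + 1]] <- list(atom = nb[r, 1], from = f$atom)
        }
      }
    }
    if (length(zs) == 0) break
    spheres <- c(spheres, paste(sprintf("%03d", sort(zs, decreasing = TRUE)),
                                collapse = ","))
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  paste(spheres, collapse = "|")
}

# Geometric R/S assignment: rank the four substituents (up to one of them an
# implicit hydrogen whose direction is taken opposite the heavy-neighbor sum)
# by the sphere signature, then take the sign of the triple product of the
# three highest-priority unit vectors; negative = clockwise viewed from
# opposite the lowest-priority substituent = R.
assign_chirality <- function(i, adj, element, nh, coords) {
  nb <- adj[[i]]
  heavy <- if (is.null(nb)) integer() else nb[, 1]
  n_sub <- length(heavy) + nh[i]
  if (n_sub != 4L || nh[i] > 1L) return("other")
  sigs <- vapply(heavy, function(a) branch_signature(a, i, adj, element, nh), "")
  vecs <- lapply(heavy, function(a) {
    v <- coords[a, ] - coords[i, ]; v / max(vec_norm(v), 1e-9)
  })
  if (nh[i] == 1L) {
    hs <- -Reduce(`+`, vecs)
    if (vec_norm(hs) < 1e-6) return("other")  # degenerate/planar geometry
    sigs <- c(sigs, "000")  # lone H: lowest priority
    vecs <- c(vecs, list(hs / vec_norm(hs)))
  }
  if (anyDuplicated(sigs)) return("other")
  ord <- order(sigs, decreasing = TRUE)
  u <- vecs[ord]
  trip <- sum(u[[1]] * c(u[[2]][2] * u[[3]][3] - u[[2]][3] * u[[3]][2],
                         u[[2]][3] * u[[3]][1] - u[[2]][1] * u[[3]][3],
                         u[[2]][1] * u[[3]][2] - u[[2]][2] * u[[3]][1]))
  if (abs(trip) < 1e-6) return("other")
  if (trip < 0) "R" else "S"
}

# Geometric E/Z assignment for a double bond between heavy atoms a1-a2.
assign_bond_stereo <- function(b, mol, adj, nh, arom_bond, in_ring) {
  if (mol$bonds$order[b] != 2 || arom_bond[b] || in_ring[b]) return("none")
  a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
  pick <- function(center, exclude) {
    nb <- adj[[center]]
    subs <- if (is.null(nb)) integer() else setdiff(nb[, 1], exclude)
    if (length(subs) == 0) return(NA_integer_)
    if (length(subs) == 1) {
      # distinguishable only if the implicit H (if any) differs from it: always true
      return(subs)
    }
    sigs <- vapply(subs, function(a) branch_signature(a, center, adj, mol$element, nh), "")
    if (anyDuplicated(sigs)) return(NA_integer_)
    subs[order(sigs, decreasing = TRUE)][1]
  }
  s1 <- pick(a1, a2); s2 <- pick(a2, a1)
  if (is.na(s1) || is.na(s2)) return("none")
  tor <- torsion_angle(mol$coords[s1, ], mol$coords[a1, ],
                       mol$coords[a2, ], mol$coords[s2, ])
  if (is.na(tor)) return("none")
  if (abs(tor) <= pi / 2) "Z" else "E"
}

# Full perception + featurization of one molfile text block.
mol_graph_from_sdf_text <- function(lines, source_id = "mol") {
  mol <- parse_molfile(lines)
  n_all <- length(mol$element)
  is_h <- mol$element == "H"
  heavy_idx <- which(!is_h)
  if (length(heavy_idx) == 0) {
    ap_abort("molecule has no heavy atoms", "affipose_parse_error", record = source_id)
  }
  # explicit H neighbors fold into the H count
  nh_explicit <- integer(n_all)
  keep_bond <- logical(nrow(mol$bonds))
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    if (is_h[a1] || is_h[a2]) {
      if (is_h[a2] && !is_h[a1]) nh_explicit[a1] <- nh_explicit[a1] + 1L
      if (is_h[a1] && !is_h[a2]) nh_explicit[a2] <- nh_explicit[a2] + 1L
    } else keep_bond[b] <- TRUE
  }
  remap <- integer(n_all); remap[heavy_idx] <- seq_along(heavy_idx)
  bonds <- mol$bonds[keep_bond, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  hm <- list(element = mol$element[heavy_idx],
             coords = mol$coords[heavy_idx, , drop = FALSE],
             charge = mol$charge[heavy_idx],
             radical = mol$radical[heavy_idx],
             bonds = bonds)
  n <- length(hm$element)
  # bond order sums (aromatic input order 4 counts 1.5)
  ord_num <- ifelse(hm$bonds$order == 4, 1.5, hm$bonds$order)
  bond_sum <- numeric(n); n_double <- integer(n); n_triple <- integer(n)
  deg <- integer(n)
  adj <- vector("list", n)
  for (b in seq_len(nrow(hm$bonds))) {
    for (side in 1:2) {
      a <- if (side == 1) hm$bonds$a1[b] else hm$bonds$a2[b]
      o <- if (side == 1) hm$bonds$a2[b] else hm$bonds$a1[b]
      bond_sum[a] <- bond_sum[a] + ord_num[b]
      deg[a] <- deg[a] + 1L
      if (hm$bonds$order[b] == 2) n_double[a] <- n_double[a] + 1L
      if (hm$bonds$order[b] == 3) n_triple[a] <- n_triple[a] + 1L
      adj[[a]] <- rbind(adj[[a]], c(o, b))
    }
  }
  # implicit hydrogens from default valence (plus any explicit H folded in)
  dv <- ELEMENT_DEFAULT_VALENCE[hm$element]
  nh_implicit <- ifelse(is.na(dv), 0,
                        pmax(0, dv + charge_valence_adjust(hm$element, hm$charge) -
                               bond_sum - hm$radical))
  nh_implicit <- floor(nh_implicit + 1e-6)
  nh <- nh_explicit[heavy_idx] + nh_implicit
  # when the file carried explicit hydrogens (3D SDF), trust them alone if the
  # valence is already satisfied
  nh <- ifelse(nh_explicit[heavy_idx] > 0 &
                 bond_sum + nh_explicit[heavy_idx] >= ifelse(is.na(dv), 0, dv),
               nh_explicit[heavy_idx], nh)
  arom <- perceive_aromatic(hm)
  # order-4 bonds in the input are explicit aromatic annotations
  if (any(hm$bonds$order == 4)) {
    b4 <- which(hm$bonds$order == 4)
    arom$bond[b4] <- TRUE
    arom$atom[unique(c(hm$bonds$a1[b4], hm$bonds$a2[b4]))] <- TRUE
  }
  ring_b <- bonds_in_ring(hm$bonds, n)
  hyb <- perceive_hybridization(hm, deg, nh, n_double, n_triple, arom$atom, bond_sum)
  # center coordinates at the heavy-atom centroid
  coords <- sweep(hm$coords, 2, colMeans(hm$coords))
  has_3d <- any(abs(coords[, 3]) > 1e-8) || n <= 2
  chir <- vapply(seq_len(n), function(i) {
    if (!has_3d) return("other")
    assign_chirality(i, adj, hm$element, nh, coords)
  }, "")
  conj <- (hyb[hm$bonds$a1] %in% c("sp", "sp2")) &
    (hyb[hm$bonds$a2] %in% c("sp", "sp2"))
  atoms <- lapply(seq_len(n), function(i) {
    list(element = hm$element[i], degree = deg[i],
         formal_charge = hm$charge[i], radical_electrons = hm$radical[i],
         hybridization = hyb[i], is_aromatic = arom$atom[i],
         num_h = nh[i], chirality = chir[i])
  })
  feats <- t(vapply(seq_len(n),
                    function(i) featurize_atom(atoms[[i]], coords[i, ]),
                    numeric(mol_node_width())))
  bond_records <- lapply(seq_len(nrow(hm$bonds)), function(b) {
    type <- if (arom$bond[b] || hm$bonds$order[b] == 4) "aromatic"
            else c("single", "double", "triple")[hm$bonds$order[b]]
    list(type = type,
         conjugated = conj[b] || arom$bond[b],
         in_ring = ring_b[b],
         stereo = assign_bond_stereo(b, hm, adj, nh, arom$bond, ring_b))
  })
  m <- nrow(hm$bonds)
  if (m > 0) {
    efeat1 <- t(vapply(bond_records, featurize_bond, numeric(mol_edge_width())))
    edge_index <- rbind(cbind(hm$bonds$a1, hm$bonds$a2),
                        cbind(hm$bonds$a2, hm$bonds$a1))
    edge_features <- rbind(efeat1, efeat1)
  } else {
    edge_index <- matrix(integer(), 0, 2)
    edge_features <- matrix(numeric(), 0, mol_edge_width())
  }
  g <- new_mol_graph(feats, edge_index, edge_features, coords, hm$element,
                     source_id, atoms = atoms,
                     bonds = if (m > 0) bond_records else list())
  # retain the absolute placement (file frame) as the centroid shift
  attr(g, "frame_shift") <- colMeans(hm$coords)
  g
}

charge_valence_adjust <- function(element, charge) {
  # +1 on N/P adds a bond slot; -1 on O/S/C removes one; symmetric default
  ifelse(element %in% c("N", "P"), charge,
         ifelse(element %in% c("O", "S", "C", "B"), -abs(charge), 0))
}

perceive_hybridization <- function(hm, deg, nh, n_double, n_triple, arom_atom,
                                   bond_sum) {
  n <- length(hm$element)
  ve <- ELEMENT_VALENCE_ELECTRONS[hm$element]
  vapply(seq_len(n), function(i) {
    if (is.na(ve[i])) return("other")          # metals / unknowns
    if (deg[i] + nh[i] == 0) return("other")   # isolated atom
    if (arom_atom[i]) return("sp2")
    if (n_triple[i] >= 1 || n_double[i] >= 2) return("sp")
    if (n_double[i] == 1) return("sp2")
    lp <- max(0, floor((ve[i] - hm$charge[i] - bond_sum[i] - nh[i]) / 2))
    steric <- deg[i] + nh[i] + lp
    if (steric <= 4) "sp3" else if (steric == 5) "sp3d"
    else if (steric == 6) "sp3d2" else "other"
  }, "")
}

# ---- readers / writers -----------------------------------------------------

#' Read a SMILES file (one record per line, optional tab-separated id)
#'
#' @param path File path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  data.frame(smiles = vapply(parts, `[`, "", 1),
             id = vapply(seq_along(parts), function(i) {
               if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%03d", i)
             }, ""),
             stringsAsFactors = FALSE)
}

#' Write a graph as a JSON dump
#'
#' Documented interchange schema shared by molecular and protein graphs:
#' `atoms` (symbols/residue names), `edges` (0-based ordered index pairs),
#' `node_feats`, `edge_feats`, `coords`. Indices are converted from the
#' package-internal 1-based convention.
#'
#' @param g A `mol_graph` or `prot_graph`.
#' @param path Output file.
#' @export
write_graph_json <- function(g, path) {
  is_mol <- inherits(g, "mol_graph")
  obj <- list(
    kind = if (is_mol) "molecule" else "protein",
    source_id = g$source_id,
    atoms = if (is_mol) g$atom_symbols else g$residue_names,
    edges = if (nrow(g$edge_index) > 0) unname(g$edge_index - 1L) else list(),
    node_feats = unname(if (is_mol) g$atom_features else g$residue_features),
    edge_feats = unname(g$edge_features),
    coords = unname(if (is_mol) g$coords else g$ca_coords)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
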