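#' Protein contact-graph featurization
#'
#' Proteins are represented at residue level as graphs \code{G_P = (N_P, E_P)}:
#' nodes are residues (plus metal ions from HETATM records), connected whenever
#' the minimal inter-atomic distance between two residues is strictly below
#' 10.0 Angstrom. Node vectors have width 31 (22-way residue-type one-hot, five
#' intra-residue distances, four backbone/side-chain dihedrals) and edge
#' vectors width 6 (2-way connectivity one-hot plus four inter-residue
#' distances). Distances are divided by the package-wide `distance_scale` of
#' 10; dihedrals are radians divided by pi so every angular feature lies in
#' \[-1, 1\].
#'
#' @name prot_graphs
NULL

PROT_RESIDUE_TYPES <- c("G", "A", "V", "L", "I", "P", "F", "Y", "W", "S",
                        "T", "C", "M", "N", "Q", "D", "E", "K", "R", "H",
                        "metal", "other")
PROT_CONTACT_CUTOFF <- 10.0
METAL_ELEMENTS <- c("ZN", "FE", "CU", "MN", "MO", "MG", "NI", "CO", "CA", "NA", "K")

AA_3TO1 <- c(GLY = "G", ALA = "A", VAL = "V", LEU = "L", ILE = "I", PRO = "P",
             PHE = "F", TYR = "Y", TRP = "W", SER = "S", THR = "T", CYS = "C",
             MET = "M", ASN = "N", GLN = "Q", ASP = "D", GLU = "E", LYS = "K",
             ARG = "R", HIS = "H")

#' Block layout of the 31-wide protein node feature vector
#'
#' @return Named list of block labels / widths, in vector order.
#' @export
prot_node_blocks <- function() {
  list(residue_type = PROT_RESIDUE_TYPES,
       distances = 5L,   # max/min atom-to-centroid, Ca-O, O-N, N-C'
       dihedrals = 4L)   # phi, psi, omega, chi1
}

#' @rdname prot_node_blocks
#' @export
prot_node_width <- function() sum(vapply(prot_node_blocks(), block_width, 1L))

#' @rdname prot_node_blocks
#' @export
prot_edge_width <- function() 6L

residue_letter <- function(res) {
  if (isTRUE(res$is_metal)) return("metal")
  l <- AA_3TO1[toupper(res$name)]
  if (is.na(l)) "other" else unname(l)
}

res_atom <- function(res, name) {
  i <- match(name, res$atom_names)
  if (is.na(i)) NULL else res$coords[i, ]
}

# first available gamma heavy atom for chi1
res_gamma_atom <- function(res) {
  for (nm in c("CG", "CG1", "OG", "OG1", "SG", "CG2")) {
    v <- res_atom(res, nm)
    if (!is.null(v)) return(v)
  }
  NULL
}

#' Featurize one residue into the 31-wide node vector
#'
#' `residue` is a record with `name` (3-letter code or element for metals),
#' `atom_names`, `coords` (\[n_atoms x 3\], Angstrom) and `is_metal`.
#' Flanking residues supply the atoms needed for phi/psi/omega; any dihedral
#' whose defining atoms are missing (chain termini, glycine chi1, metals) is
#' encoded as 0.
#'
#' @param residue Residue record.
#' @param prev,nxt Flanking residue records or `NULL`.
#' @return Numeric vector of length 31.
#' @export
featurize_residue <- function(residue, prev = NULL, nxt = NULL) {
  letter <- residue_letter(residue)
  has_backbone <- !is.null(res_atom(residue, "N")) &&
    !is.null(res_atom(residue, "CA")) && !is.null(res_atom(residue, "C"))
  if (!isTRUE(residue$is_metal) && !has_backbone &&
      is.null(res_atom(residue, "O"))) {
    ap_abort(sprintf("residue '%s' lacks backbone atoms and is not a metal",
                     residue$name), "affipose_invalid_residue")
  }
  type <- one_hot(letter, PROT_RESIDUE_TYPES, other = "other")
  dists <- numeric(5)
  dihs <- numeric(4)
  if (!isTRUE(residue$is_metal)) {
    centroid <- colMeans(residue$coords)
    dc <- sqrt(rowSums(sweep(residue$coords, 2, centroid)^2))
    dists[1] <- max(dc)
    dists[2] <- min(dc)
    ca <- res_atom(residue, "CA"); o <- res_atom(residue, "O")
    nn <- res_atom(residue, "N"); cc <- res_atom(residue, "C")
    if (!is.null(ca) && !is.null(o)) dists[3] <- vec_norm(ca - o)
    if (!is.null(o) && !is.null(nn)) dists[4] <- vec_norm(o - nn)
    if (!is.null(nn) && !is.null(cc)) dists[5] <- vec_norm(nn - cc)
    # phi: C'(i-1) - N - CA - C'
    if (!is.null(prev) && !isTRUE(prev$is_metal)) {
      pc <- res_atom(prev, "C"); pca <- res_atom(prev, "CA")
      if (!is.null(pc) && !is.null(nn) && !is.null(ca) && !is.null(cc)) {
        dihs[1] <- torsion_angle(pc, nn, ca, cc) %|NA|% 0
      }
      # omega: CA(i-1) - C'(i-1) - N - CA
      if (!is.null(pca) && !is.null(pc) && !is.null(nn) && !is.null(ca)) {
        dihs[3] <- torsion_angle(pca, pc, nn, ca) %|NA|% 0
      }
    }
    # psi: N - CA - C' - N(i+1)
    if (!is.null(nxt) && !isTRUE(nxt$is_metal)) {
      nx <- res_atom(nxt, "N")
      if (!is.null(nn) && !is.null(ca) && !is.null(cc) && !is.null(nx)) {
        dihs[2] <- torsion_angle(nn, ca, cc, nx) %|NA|% 0
      }
    }
    # chi1: N - CA - CB - CG
    cb <- res_atom(residue, "CB"); cg <- res_gamma_atom(residue)
    if (!is.null(nn) && !is.null(ca) && !is.null(cb) && !is.null(cg)) {
      dihs[4] <- torsion_angle(nn, ca, cb, cg) %|NA|% 0
    }
  }
  c(type, dists / DISTANCE_SCALE, dihs / pi)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Contact edges between residues under the 10 Angstrom rule
#'
#' An edge exists between two distinct residues iff the minimal distance
#' between any atom pair is strictly below `cutoff`. Each contact is stored
#' in both directions with identical features: connectivity one-hot (1, 0),
#' then Ca-Ca, centroid, max and min inter-residue atomic distances, divided
#' by `distance_scale`. For metal nodes the single ion coordinate stands in
#' for Ca.
#'
#' @param residues List of residue records (see [featurize_residue()]).
#' @param cutoff Contact cutoff in Angstrom (default 10.0, strict `<`).
#' @return List with `edge_index` (\[m x 2\], both directions) and
#'   `edge_features` (\[m x 6\]).
#' @export
contact_edges <- function(residues, cutoff = PROT_CONTACT_CUTOFF) {
  n <- length(residues)
  cents <- t(vapply(residues, function(r) colMeans(r$coords), numeric(3)))
  cas <- t(vapply(residues, function(r) {
    ca <- res_atom(r, "CA")
    if (is.null(ca)) colMeans(r$coords) else ca
  }, numeric(3)))
  radii <- vapply(seq_len(n), function(i) {
    max(sqrt(rowSums(sweep(residues[[i]]$coords, 2, cents[i, ])^2)))
  }, 0)
  idx <- matrix(integer(), 0, 2)
  feats <- matrix(numeric(), 0, prot_edge_width())
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lower_bound <- vec_norm(cents[i, ] - cents[j, ]) - radii[i] - radii[j]
        if (lower_bound >= cutoff) next
        mm <- pairwise_min_max_dist(residues[[i]]$coords, residues[[j]]$coords)
        if (mm$min < cutoff) {
          f <- c(1, 0,
                 vec_norm(cas[i, ] - cas[j, ]) / DISTANCE_SCALE,
                 vec_norm(cents[i, ] - cents[j, ]) / DISTANCE_SCALE,
                 mm$max / DISTANCE_SCALE,
                 mm$min / DISTANCE_SCALE)
          idx <- rbind(idx, c(i, j), c(j, i))
          feats <- rbind(feats, f, f)
        }
      }
    }
  }
  rownames(feats) <- NULL
  list(edge_index = idx, edge_features = feats)
}

new_prot_graph <- function(residue_features, edge_index, edge_features,
                           residue_names, ca_coords, source_id,
                           residues = NULL, sequence = NULL) {
  g <- structure(list(residue_features = residue_features,
                      edge_index = edge_index,
                      edge_features = edge_features,
                      residue_names = residue_names,
                      ca_coords = ca_coords,
                      source_id = source_id,
                      residues = residues,
                      sequence = sequence),
                 class = "prot_graph")
  validate_prot_graph(g)
  g
}

#' Validate the invariants of a protein graph
#' @param g A `prot_graph`.
#' @return The graph, invisibly.
#' @export
validate_prot_graph <- function(g) {
  n <- nrow(g$residue_features)
  if (n < 1L) ap_abort("protein must have at least one residue", "affipose_invalid_input")
  if (ncol(g$residue_features) != prot_node_width())
    ap_abort("residue_features width != 31", "affipose_dimension_error")
  if (nrow(g$edge_index) > 0) {
    if (ncol(g$edge_features) != prot_edge_width())
      ap_abort("edge_features width != 6", "affipose_dimension_error")
    if (any(g$edge_index[, 1] == g$edge_index[, 2]))
      ap_abort("self contact edge", "affipose_invalid_input")
    key <- paste(g$edge_index[, 1], g$edge_index[, 2])
    if (!setequal(key, paste(g$edge_index[, 2], g$edge_index[, 1])))
      ap_abort("contact edges not symmetric", "affipose_invalid_input")
  }
  invisible(g)
}

#' @export
print.prot_graph <- function(x, ...) {
  cat(sprintf("<prot_graph %s: %d residues, %d directed edges>\n",
              x$source_id, nrow(x$residue_features), nrow(x$edge_index)))
  invisible(x)
}

#' Build a protein graph from residue records
#'
#' @param residues List of residue records in chain order.
#' @param source_id Identifier.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `prot_graph`. The attached `sequence` has one letter per node
#'   ("X" for metals and non-standard residues) so that per-residue embedding
#'   rows align with graph nodes.
#' @export
prot_graph_from_residues <- function(residues, source_id = "prot",
                                     cutoff = PROT_CONTACT_CUTOFF) {
  n <- length(residues)
  feats <- t(vapply(seq_len(n), function(i) {
    featurize_residue(residues[[i]],
                      prev = if (i > 1) residues[[i - 1]] else NULL,
                      nxt = if (i < n) residues[[i + 1]] else NULL)
  }, numeric(prot_node_width())))
  if (n == 1) feats <- matrix(feats, 1)
  edges <- contact_edges(residues, cutoff)
  cas <- t(vapply(residues, function(r) {
    ca <- res_atom(r, "CA"); if (is.null(ca)) colMeans(r$coords) else ca
  }, numeric(3)))
  letters1 <- vapply(residues, residue_letter, "")
  seq1 <- ifelse(letters1 %in% c("metal", "other"), "X", letters1)
  new_prot_graph(feats, edges$edge_index, edges$edge_features,
                 vapply(residues, function(r) r$name, ""),
                 cas, source_id, residues = residues,
                 sequence = paste(seq1, collapse = ""))
}

#' Build a protein graph from a PDB file
#'
#' Standard residues come from ATOM records; metal ions are recognized from
#' HETATM element symbols (ZN, FE, CU, MN, MO, ...). Waters and organic
#' heteroatoms are ignored. Alternate locations resolve to the
#' highest-occupancy conformer; insertion-coded residues are kept in file
#' order. Residue indexing is 0-based internally; PDB author numbering is
#' retained only as metadata.
#'
#' @param path PDB file path.
#' @param chain_policy "first_chain" (default) or "all_chains".
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `prot_graph`.
#' @export
prot_graph_from_pdb <- function(path,
                                chain_policy = c("first_chain", "all_chains"),
                                cutoff = PROT_CONTACT_CUTOFF) {
  chain_policy <- match.arg(chain_policy)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) NULL)
  if (is.null(pdb)) {
    ap_abort(sprintf("no parseable residues in '%s'", path), "affipose_empty_structure")
  }
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  is_std <- at$type == "ATOM" & toupper(at$resid) %in% names(AA_3TO1)
  is_metal <- at$type == "HETATM" & toupper(at$elesy) %in% METAL_ELEMENTS
  # non-standard polymer residues with backbone atoms -> "other" nodes
  is_other <- at$type == "ATOM" & !is_std
  at <- at[is_std | is_metal | is_other, , drop = FALSE]
  if (nrow(at) == 0) {
    ap_abort(sprintf("no parseable residues in '%s'", path), "affipose_empty_structure")
  }
  if (chain_policy == "first_chain") {
    at <- at[at$chain == at$chain[1], , drop = FALSE]
  }
  # altloc: keep highest occupancy per (chain, resno, insert, elety)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert),
                       unique(paste(at$chain, at$resno, at$insert)))), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert)
  residues <- lapply(unique(rkey), function(k) {
    rows <- at[rkey == k, , drop = FALSE]
    metal <- rows$type[1] == "HETATM"
    list(name = if (metal) toupper(rows$elesy[1]) else toupper(rows$resid[1]),
         atom_names = rows$elety,
         coords = cbind(rows$x, rows$y, rows$z),
         is_metal = metal,
         author_number = rows$resno[1],
         chain = rows$chain[1])
  })
  # drop polymer residues without any backbone atom (featurize would reject)
  keep <- vapply(residues, function(r) {
    r$is_metal || any(c("N", "CA", "C", "O") %in% r$atom_names)
  }, TRUE)
  residues <- residues[keep]
  if (length(residues) == 0) {
    ap_abort(sprintf("no parseable residues in '%s'", path), "affipose_empty_structure")
  }
  prot_graph_from_residues(residues, source_id = basename(path), cutoff = cutoff)
}

#' Integer-encode a protein sequence to fixed length
#'
#' Letters map alphabetically: A=1, C=2, D=3, ..., Y=20; `X` or any letter
#' outside the 20-letter alphabet takes the last code (20). Sequences shorter
#' than `N` are zero-padded (0 is the pad symbol); longer sequences keep their
#' `N`-prefix.
#'
#' @param seq Amino-acid string.
#' @param N Fixed encoding length (default 1000).
#' @return List with `codes` (integer vector of length `N`) and `true_length`.
#' @export
encode_sequence <- function(seq, N = 1000L) {
  if (!nzchar(seq)) ap_abort("empty sequence", "affipose_invalid_input")
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) > N) chars <- chars[seq_len(N)]
  codes <- match(chars, alphabet)
  codes[is.na(codes)] <- 20L
  out <- integer(N)
  out[seq_along(codes)] <- codes
  list(codes = out, true_length = length(codes))
}

#' @rdname write_graph_json
#' @export
write_prot_graph_json <- function(g, path) write_graph_json(g, path)
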