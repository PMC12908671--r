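#' Pose-set assembly and RMSD labelling
#'
#' Decoy poses are labelled by their coordinate RMSD to the native pose,
#' computed in the shared receptor frame with fixed atom ordering and no
#' superposition (symmetry-corrected RMSD is out of scope and documented as a
#' limitation).
#'
#' @name pose_tools
NULL

#' Coordinate RMSD between two poses
#'
#' @param coords_a,coords_b Matrices \[n x 3\] in Angstrom, same atom order.
#' @return `sqrt(mean(rowwise squared displacement))` in Angstrom.
#' @export
pose_rmsd <- function(coords_a, coords_b) {
  if (!is.matrix(coords_a) || !is.matrix(coords_b) ||
      nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3 || ncol(coords_b) != 3) {
    ap_abort("pose_rmsd needs two [n x 3] matrices with matching atom counts",
             "affipose_invalid_input")
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

new_complex_record <- function(mol, prot, affinity, rmsd_label, is_native,
                               complex_id, pose_id, mol_offset = c(0, 0, 0)) {
  structure(list(mol = mol, prot = prot,
                 affinity = affinity, rmsd_label = rmsd_label,
                 is_native = is_native,
                 near_native = if (is.na(rmsd_label)) NA else rmsd_label <= NEAR_NATIVE_RMSD,
                 complex_id = complex_id, pose_id = pose_id,
                 mol_offset = mol_offset),
            class = "complex_record")
}

#' Label a native + decoy pose set as complex records
#'
#' One record per pose including the native (RMSD 0, `is_native` set). Each
#' record also carries a `near_native` flag (true RMSD <= 2.0 Angstrom) used
#' by the evaluation splits that include or exclude native structures.
#'
#' @param native A `mol_graph` holding the native pose.
#' @param decoys List of `mol_graph` poses sharing the native's atom order.
#' @param prot A `prot_graph`.
#' @param affinity Binding affinity label (or NA).
#' @param complex_id Identifier for the complex.
#' @param mol_offset Placement of the molecule centroid in the protein frame.
#' @return List of `complex_record`s, the native first.
#' @export
label_pose_set <- function(native, decoys, prot, affinity = NA_real_,
                           complex_id = native$source_id,
                           mol_offset = c(0, 0, 0)) {
  for (k in seq_along(decoys)) {
    d <- decoys[[k]]
    if (nrow(d$coords) != nrow(native$coords) ||
        !identical(d$atom_symbols, native$atom_symbols)) {
      ap_abort(sprintf("pose %d does not share the native atom ordering", k),
               "affipose_invalid_input", pose = k)
    }
  }
  records <- list(new_complex_record(native, prot, affinity, 0,
                                     TRUE, complex_id, "native", mol_offset))
  for (k in seq_along(decoys)) {
    r <- pose_rmsd(native_frame_coords(native), native_frame_coords(decoys[[k]]))
    records[[k + 1]] <- new_complex_record(decoys[[k]], prot, affinity, r,
                                           FALSE, complex_id,
                                           sprintf("decoy%02d", k), mol_offset)
  }
  records
}

# Poses carry centroid-centered coords (featurization contract); the rigid
# placement relative to the native frame is kept in the "frame_shift"
# attribute so RMSD sees the true displacement.
native_frame_coords <- function(mol) {
  shift <- attr(mol, "frame_shift") %||% c(0, 0, 0)
  sweep(mol$coords, 2, shift, `+`)
}

#' Drop the native record from a pose set (evaluation without natives)
#'
#' @param records List of `complex_record`s.
#' @return The records whose `is_native` flag is FALSE.
#' @export
exclude_native <- function(records) {
  records[!vapply(records, function(r) isTRUE(r$is_native), TRUE)]
}
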