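#' Template complex for two-step docking
#'
#' A template structure with a bound ligand, a global transform aligning the
#' template onto the target, and an injective chemical mapping from template
#' ligand atoms to drug atoms.
#'
#' @param structure Template [mol_structure()].
#' @param ligand Template-bound `small_mol` with coordinates.
#' @param transform [rigid_transform()] mapping template frame to target
#'   frame.
#' @param mapping Tibble with columns `template_atom`, `drug_atom` (heavy-atom
#'   indices).
#' @return An object of class `template_complex`.
#' @export
template_complex <- function(structure, ligand, transform, mapping) {
  mapping <- as_tibble(mapping)
  if (anyDuplicated(mapping$template_atom) || anyDuplicated(mapping$drug_atom)) {
    abort("chemical mapping must be injective on heavy atoms")
  }
  structure(
    list(structure = structure, ligand = ligand, transform = transform,
      mapping = mapping),
    class = "template_complex"
  )
}

#' Drug pose
#'
#' A drug molecule with coordinates in a target's frame plus provenance (the
#' source target and the alignment or template that produced it).
#'
#' @param drug `small_mol` with coordinates.
#' @param source_id Source target identifier.
#' @param via Alignment or template identifier.
#' @return An object of class `drug_pose`.
#' @export
drug_pose <- function(drug, source_id = NA_character_, via = NA_character_) {
  if (!mol_has_coords(drug)) abort("a drug pose needs coordinates on all heavy atoms")
  structure(
    list(drug = drug, provenance = list(source_id = source_id, via = via)),
    class = "drug_pose"
  )
}

#' @export
print.drug_pose <- function(x, ...) {
  cat(sprintf(
    "<drug_pose %s> %d heavy atoms, from %s via %s\n",
    x$drug$id, nrow(x$drug$atoms),
    x$provenance$source_id, x$provenance$via
  ))
  invisible(x)
}

#' Template-based docking of a drug into a target
#'
#' Two-step similarity-based docking: the template-bound ligand is moved into
#' the target frame by the supplied global transform, the drug's mapped atoms
#' are fitted onto the mapped template-ligand atoms by least squares, and
#' unmapped drug atoms are carried rigidly by the same fitted transform.
#'
#' @param target [mol_structure()] the pose is built for.
#' @param tc A [template_complex()].
#' @param drug `small_mol` with its own 3D conformation.
#' @return A [drug_pose()] in the target frame.
#' @export
template_dock <- function(target, tc, drug) {
  if (nrow(tc$mapping) < 3) {
    abort("chemical mapping must cover at least 3 atoms")
  }
  lig_xyz <- apply_transform(tc$transform, mol_coords(tc$ligand))
  drug_xyz <- mol_coords(drug)
  fit <- kabsch_superpose(
    drug_xyz[tc$mapping$drug_atom, , drop = FALSE],
    lig_xyz[tc$mapping$template_atom, , drop = FALSE]
  )
  posed <- apply_transform(fit$transform, drug_xyz)
  drug_pose(
    mol_set_coords(drug, posed),
    source_id = tc$structure$id,
    via = paste0("template:", tc$ligand$id)
  )
}

#' Transfer a pose through a pocket alignment
#'
#' Applies the rigid transform of a source-to-destination pocket alignment to
#' every atom of a pose; a rigid motion, so all intra-ligand distances are
#' preserved exactly.
#'
#' @param pose A [drug_pose()] in the source frame.
#' @param alignment A [pocket_alignment()] (source onto destination); must
#'   not be flagged failed.
#' @param alignment_id Identifier recorded in the provenance.
#' @return A [drug_pose()] in the destination frame.
#' @export
transfer_by_alignment <- function(pose, alignment, alignment_id = "alignment") {
  if (alignment$failed) abort("cannot transfer through a failed alignment")
  moved <- apply_transform(alignment$transform, mol_coords(pose$drug))
  drug_pose(
    mol_set_coords(pose$drug, moved),
    source_id = pose$provenance$source_id,
    via = alignment_id
  )
}

#' Detect steric clashes between a pose and a structure
#'
#' All protein-heavy/ligand-heavy atom pairs strictly closer than
#' `clash_cutoff` (default 2.5 Angstrom; a pair at exactly the cutoff is not
#' a clash).
#'
#' @param pose A [drug_pose()] or `small_mol` with coordinates.
#' @param structure A [mol_structure()].
#' @param clash_cutoff Distance cutoff in Angstrom.
#' @return Tibble with columns `protein_serial`, `ligand_atom`, `distance`.
#' @export
detect_clashes <- function(pose, structure, clash_cutoff = 2.5) {
  mol <- if (inherits(pose, "drug_pose")) pose$drug else pose
  lig <- mol_coords(mol)
  a <- structure$atoms %>% filter(.data$element != "H")
  prot <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(prot^2), rowSums(lig^2), "+") - 2 * prot %*% t(lig)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d < clash_cutoff, arr.ind = TRUE)
  tibble(
    protein_serial = a$serial[hit[, 1]],
    ligand_atom = as.integer(hit[, 2]),
    distance = d[hit]
  ) %>% arrange(.data$distance)
}

clash_penalty <- function(lig, prot, cutoff) {
  d2 <- outer(rowSums(prot^2), rowSums(lig^2), "+") - 2 * prot %*% t(lig)
  d <- sqrt(pmax(d2, 0))
  over <- pmax(cutoff - d, 0)
  sum(over^2)
}

clash_gradient <- function(lig, prot, cutoff) {
  d2 <- outer(rowSums(prot^2), rowSums(lig^2), "+") - 2 * prot %*% t(lig)
  d <- sqrt(pmax(d2, 1e-12))
  hit <- which(d < cutoff, arr.ind = TRUE)
  g <- c(0, 0, 0)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]
    j <- hit[k, 2]
    unit <- (lig[j, ] - prot[i, ]) / d[hit[k, , drop = FALSE]]
    g <- g - 2 * (cutoff - d[hit[k, , drop = FALSE]]) * unit
  }
  g
}

#' Rigid-body clash relief
#'
#' Greedy steepest-descent translation of the whole ligand on the
#' clash-overlap penalty `sum((cutoff - d)^2)` over clashing pairs, in steps
#' of `step` Angstrom, until the pose is clash-free, the penalty stops
#' decreasing, or the total displacement reaches `max_translation`.  The
#' ligand's internal geometry is never altered; failure to fully relieve is
#' expressed through the residual clash report, not an error.
#'
#' @param pose A [drug_pose()].
#' @param structure A [mol_structure()].
#' @param clash_cutoff Clash distance in Angstrom (default 2.5).
#' @param max_translation Displacement cap in Angstrom (default 3).
#' @param step Step length in Angstrom (default 0.1).
#' @return List with elements `pose` (refined [drug_pose()]), `clashes`
#'   (residual-clash tibble), `displacement` (Angstrom moved) and `relieved`
#'   flag.
#' @export
relieve_clashes <- function(pose, structure, clash_cutoff = 2.5,
                            max_translation = 3, step = 0.1) {
  a <- structure$atoms %>% filter(.data$element != "H")
  prot <- as.matrix(a[, c("x", "y", "z")])
  lig0 <- mol_coords(pose$drug)
  shift <- c(0, 0, 0)
  pen <- clash_penalty(lig0, prot, clash_cutoff)
  while (pen > 0 && sqrt(sum(shift^2)) < max_translation - 1e-12) {
    lig <- sweep(lig0, 2, -shift)
    g <- clash_gradient(lig, prot, clash_cutoff)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break # symmetric cage: no descent direction
    proposal <- shift - step * g / gn
    if (sqrt(sum(proposal^2)) > max_translation) {
      proposal <- proposal * max_translation / sqrt(sum(proposal^2))
    }
    new_pen <- clash_penalty(sweep(lig0, 2, -proposal), prot, clash_cutoff)
    if (new_pen >= pen) break
    shift <- proposal
    pen <- new_pen
  }
  refined <- drug_pose(
    mol_set_coords(pose$drug, sweep(lig0, 2, -shift)),
    source_id = pose$provenance$source_id,
    via = pose$provenance$via
  )
  clashes <- detect_clashes(refined, structure, clash_cutoff)
  list(
    pose = refined, clashes = clashes,
    displacement = sqrt(sum(shift^2)),
    relieved = nrow(clashes) == 0
  )
}

#' Consensus over multiple poses of one drug
#'
#' Pairwise heavy-atom RMSD matrix over poses sharing the destination frame
#' (no re-superposition: superposing would erase the binding-mode difference
#' being measured), per-pose mean RMSD to the others ("spread"), and the most
#' typical pose (minimal spread; ties resolved to the lowest index).
#'
#' @param poses List of at least 2 [drug_pose()] objects of the same drug.
#' @param mapping Optional integer vector of common heavy-atom indices
#'   (default: all atoms of the first pose).
#' @return An object of class `consensus_result`.
#' @export
consensus_pose <- function(poses, mapping = NULL) {
  if (length(poses) < 2) abort("consensus needs at least 2 poses")
  xyz <- map(poses, function(p) {
    m <- mol_coords(p$drug)
    if (!is.null(mapping)) m[mapping, , drop = FALSE] else m
  })
  n_atoms <- unique(map_int(xyz, nrow))
  if (length(n_atoms) != 1) {
    abort("poses do not share a common atom mapping")
  }
  k <- length(poses)
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- rmsd_paired(xyz[[i]], xyz[[j]], superpose = FALSE)
    }
  }
  spread <- rowSums(m) / (k - 1)
  typical <- which.min(spread) # which.min takes the first (lowest index) tie
  structure(
    list(
      typical_index = typical, rmsd_matrix = m, spread = spread,
      n_poses = k
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d poses, typical pose #%d (spread %.2f A)\n",
    x$n_poses, x$typical_index, x$spread[x$typical_index]
  ))
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(
    pose = seq_len(x$n_poses),
    spread = x$spread,
    typical = seq_len(x$n_poses) == x$typical_index
  )
}
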