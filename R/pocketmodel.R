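# Residue-level feature tables used by the pocket similarity score:
# Kyte-Doolittle hydropathy, charge class at neutral pH, polarity and
# aromaticity flags, and heavy side-chain atom counts.
KD_HYDROPATHY <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
  LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2
)
CHARGE_CLASS <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)
POLAR_RES <- c(
  "SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS",
  "ASP", "GLU", "LYS", "ARG"
)
AROMATIC_RES <- c("PHE", "TRP", "TYR", "HIS")
SIDECHAIN_SIZE <- c(
  ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5, GLU = 5,
  GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5, MET = 4, PHE = 7,
  PRO = 3, SER = 2, THR = 3, TRP = 10, TYR = 8, VAL = 3
)

#' Physicochemical features of a residue type
#'
#' @param res_name Character vector of 3-letter residue codes.
#' @param conservation Evolutionary conservation weight in \[0, 1\]; defaults
#'   to the uninformative 1.0.
#' @return Tibble with columns `hydrophobicity`, `charge_class`, `polar`,
#'   `aromatic`, `side_chain_size`, `conservation`.
#' @export
residue_features <- function(res_name, conservation = 1) {
  res_name <- toupper(res_name)
  tibble(
    hydrophobicity = unname(ifelse(res_name %in% names(KD_HYDROPATHY),
      KD_HYDROPATHY[res_name], 0)),
    charge_class = unname(ifelse(res_name %in% names(CHARGE_CLASS),
      CHARGE_CLASS[res_name], 0)),
    polar = res_name %in% POLAR_RES,
    aromatic = res_name %in% AROMATIC_RES,
    side_chain_size = unname(ifelse(res_name %in% names(SIDECHAIN_SIZE),
      SIDECHAIN_SIZE[res_name], 1)),
    conservation = rep_len(pmin(pmax(conservation, 0), 1), length(res_name))
  )
}

#' Binding-pocket object
#'
#' A set of binding residues with Calpha coordinates and physicochemical
#' features, a pocket center, and a prediction confidence.  Pockets with at
#' least 5 residues are eligible for alignment.
#'
#' @param target_id Identifier of the parent target.
#' @param residues Tibble with columns `chain`, `resnum`, `icode`, `res_name`,
#'   `ca_x`, `ca_y`, `ca_z` plus the [residue_features()] columns.
#' @param center Numeric 3-vector (Angstrom).
#' @param confidence Percentage in \[0, 100\].
#' @param profile Optional ligand property profile (see [property_profile()]).
#' @return An object of class `pocket`.
#' @export
new_pocket <- function(target_id, residues, center, confidence = 100,
                       profile = NULL) {
  residues <- as_tibble(residues)
  if (!all(is.finite(center)) || length(center) != 3) {
    abort("pocket center must be a finite 3-vector")
  }
  structure(
    list(
      target_id = target_id, residues = residues,
      center = as.numeric(center), confidence = as.numeric(confidence),
      profile = profile
    ),
    class = "pocket"
  )
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf(
    "<pocket %s> %d residues, confidence %.1f%%, center (%.1f, %.1f, %.1f)\n",
    x$target_id, nrow(x$residues), x$confidence,
    x$center[1], x$center[2], x$center[3]
  ))
  invisible(x)
}

#' Calpha coordinates of a pocket
#' @param pocket A [new_pocket()] object.
#' @return n x 3 matrix.
#' @export
pocket_coords <- function(pocket) {
  unname(as.matrix(pocket$residues[, c("ca_x", "ca_y", "ca_z")]))
}

#' Extract the binding pocket around a bound ligand
#'
#' Selects every residue with at least one heavy atom within `cutoff` of any
#' ligand heavy atom (the conventional contact definition of "actual" binding
#' residues).  The pocket center is the geometric center of the ligand's heavy
#' atoms.
#'
#' @param structure A [mol_structure()].
#' @param ligand A `small_mol` with coordinates.
#' @param cutoff Heavy-atom contact distance in Angstrom (default 4.5).
#' @param conservation Conservation weight applied to all residues (default 1).
#' @return A [new_pocket()].
#' @export
extract_pocket <- function(structure, ligand, cutoff = 4.5, conservation = 1) {
  if (cutoff <= 0) abort("cutoff must be positive")
  lig_xyz <- mol_coords(ligand)
  a <- structure$atoms %>% filter(.data$element != "H")
  prot_xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
    2 * prot_xyz %*% t(lig_xyz)
  in_contact <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
  if (!any(in_contact)) {
    abort(sprintf("no residue within %.2f A of ligand %s", cutoff, ligand$id))
  }
  contact_res <- a[in_contact, ] %>%
    distinct(.data$chain, .data$resnum, .data$icode)
  res <- structure_residues(structure) %>%
    inner_join(contact_res, by = c("chain", "resnum", "icode"))
  if (anyNA(res$ca_x)) {
    abort("contact residues without Calpha atoms cannot form a pocket")
  }
  res <- bind_cols(res, residue_features(res$res_name, conservation))
  new_pocket(
    target_id = structure$id, residues = res,
    center = colMeans(lig_xyz), confidence = 100
  )
}

#' Build a pocket from an annotation
#'
#' Resolves every annotated residue in the structure; the pocket center is the
#' annotation's center when present, otherwise the centroid of the annotated
#' Calpha atoms.
#'
#' @param structure A [mol_structure()].
#' @param annotation A [pocket_annotation()].
#' @param conservation Conservation weight (default 1).
#' @return A [new_pocket()].
#' @export
pocket_from_annotation <- function(structure, annotation, conservation = 1) {
  res_tab <- structure_residues(structure)
  ann <- annotation$residues
  if (!"icode" %in% names(ann)) ann$icode <- ""
  hit <- left_join(
    ann,
    mutate(res_tab, .found = TRUE),
    by = c("chain", "resnum", "icode")
  )
  bad <- is.na(hit$.found) | toupper(hit$resname) != toupper(hit$res_name)
  if (any(bad)) {
    abort(paste0(
      "annotation residues not resolvable in ", structure$id, ": ",
      paste(sprintf("%s/%d %s", ann$chain[bad], ann$resnum[bad],
        ann$resname[bad]), collapse = ", ")
    ))
  }
  if (anyNA(hit$ca_x)) abort("annotated residues lack Calpha atoms")
  res <- hit %>%
    select("chain", "resnum", "icode", res_name = "res_name",
      "ca_x", "ca_y", "ca_z")
  res <- bind_cols(res, residue_features(res$res_name, conservation))
  center <- annotation$center %||%
    colMeans(as.matrix(res[, c("ca_x", "ca_y", "ca_z")]))
  new_pocket(
    target_id = annotation$target_id, residues = res,
    center = center, confidence = annotation$confidence
  )
}

#' Is a pocket annotation correct for a bound ligand?
#'
#' An annotation counts as correct when its center lies within `threshold`
#' (default 8 Angstrom, boundary inclusive) of the geometric center of the
#' bound ligand's heavy atoms.
#'
#' @param pocket_center Numeric 3-vector.
#' @param ligand A `small_mol` with coordinates.
#' @param threshold Distance threshold in Angstrom.
#' @return Logical flag.
#' @export
annotation_is_correct <- function(pocket_center, ligand, threshold = 8) {
  lig_center <- colMeans(mol_coords(ligand))
  sqrt(sum((pocket_center - lig_center)^2)) <= threshold
}

#' Radius of gyration of a ligand
#'
#' Geometric (mass-unweighted) radius of gyration over heavy atoms: the root
#' mean squared distance from the heavy-atom centroid.
#'
#' @param ligand A `small_mol` with coordinates and at least 2 heavy atoms.
#' @return Radius of gyration in Angstrom.
#' @export
ligand_radius_of_gyration <- function(ligand) {
  xyz <- mol_coords(ligand)
  if (nrow(xyz) < 2) abort("radius of gyration needs at least 2 heavy atoms")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Docking search-box edge from a ligand's radius of gyration
#'
#' Cubic search space centered on the binding site, with edge 2.9 times the
#' radius of gyration, floored at 22.5 Angstrom.
#'
#' @param rg Radius of gyration in Angstrom (> 0).
#' @return Cube edge length in Angstrom.
#' @export
search_box_from_rg <- function(rg) {
  if (any(rg <= 0)) abort("radius of gyration must be positive")
  pmax(2.9 * rg, 22.5)
}

#' Property profile of a set of ligands
#'
#' Mean and population standard deviation of molecular weight, Crippen logP
#' and Ertl TPSA over a set of predicted binders; the profile a pocket's
#' binders present to the matcher.
#'
#' @param ligands Non-empty list of `small_mol` objects.
#' @return An object of class `ligand_profile` with fields `mw_mean`, `mw_sd`,
#'   `logp_mean`, `logp_sd`, `psa_mean`, `psa_sd`.
#' @export
property_profile <- function(ligands) {
  if (!length(ligands)) abort("at least one ligand is required")
  desc <- imap(ligands, function(l, i) {
    tryCatch(
      tibble(mw = molecular_weight(l), logp = clogp(l), psa = tpsa(l)),
      error = function(e) {
        abort(paste0("descriptor failure on ligand ", l$id %||% i, ": ",
          conditionMessage(e)))
      }
    )
  })
  d <- bind_rows(desc)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(
      mw_mean = mean(d$mw), mw_sd = pop_sd(d$mw),
      logp_mean = mean(d$logp), logp_sd = pop_sd(d$logp),
      psa_mean = mean(d$psa), psa_sd = pop_sd(d$psa),
      n = nrow(d)
    ),
    class = "ligand_profile"
  )
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat(sprintf(
    "<ligand_profile> n = %d: MW %.1f +/- %.1f Da, logP %.2f +/- %.2f, PSA %.1f +/- %.1f A^2\n",
    x$n, x$mw_mean, x$mw_sd, x$logp_mean, x$logp_sd, x$psa_mean, x$psa_sd
  ))
  invisible(x)
}

#' Map a numeric confidence to a tier label
#'
#' @param confidence Percentage in \[0, 100\].
#' @param thresholds Named vector with the lower bounds of the `high` and
#'   `moderate` tiers (defaults: 80 and 50).
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
confidence_tier <- function(confidence, thresholds = c(high = 80, moderate = 50)) {
  ifelse(confidence >= thresholds[["high"]], "high",
    ifelse(confidence >= thresholds[["moderate"]], "moderate", "low")
  )
}

#' Write pockets to a TSV mirroring the annotation format
#' @param pockets List of `pocket` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pockets <- function(pockets, path) {
  rows <- bind_rows(map(pockets, function(p) {
    tibble(
      target_id = p$target_id, chain = p$residues$chain,
      resnum = p$residues$resnum, resname = p$residues$res_name,
      confidence = p$confidence
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
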