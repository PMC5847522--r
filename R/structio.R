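#' Molecular structure container
#'
#' Holds a protein structure as a tidy atom table plus extracted ligands.
#' Residue identity is the triple (chain, residue number, insertion code) in
#' author numbering; no renumbering is ever applied.  Hetero groups with at
#' least four heavy atoms (waters always excluded) are exposed as
#' [small_molecule()] ligands; smaller hetero groups (ions, buffers) stay in
#' the `het` table.
#'
#' @param atoms Tibble of protein ATOM records with columns `serial`, `name`,
#'   `altloc`, `res_name`, `chain`, `resnum`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `hetero`.
#' @param ligands List of `small_mol` ligands.
#' @param het Tibble of non-ligand hetero atoms (same columns as `atoms`).
#' @param id Structure identifier.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, ligands = list(), het = NULL, id = "structure") {
  atoms <- as_tibble(atoms)
  n_het <- if (is.null(het)) 0L else nrow(het)
  if (nrow(atoms) == 0 && length(ligands) == 0 && n_het == 0) {
    abort("empty structure")
  }
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name)
  if (anyDuplicated(key)) abort("duplicate atom name within a residue")
  structure(
    list(
      id = id, atoms = atoms,
      het = het %||% atoms[0, ],
      ligands = ligands
    ),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  nres <- nrow(dplyr::distinct(x$atoms, .data$chain, .data$resnum, .data$icode))
  cat(sprintf(
    "<mol_structure %s> %d chains, %d residues, %d atoms, %d ligand(s)\n",
    x$id, length(unique(x$atoms$chain)), nres, nrow(x$atoms), length(x$ligands)
  ))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure A `mol_structure`.
#' @return Tibble with one row per residue: chain, resnum, icode, res_name and
#'   Calpha coordinates (NA when no CA atom is present).
#' @export
structure_residues <- function(structure) {
  ca <- structure$atoms %>%
    filter(.data$name == "CA") %>%
    select("chain", "resnum", "icode", ca_x = "x", ca_y = "y", ca_z = "z")
  structure$atoms %>%
    distinct(.data$chain, .data$resnum, .data$icode, .data$res_name) %>%
    left_join(ca, by = c("chain", "resnum", "icode"))
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (ln in coord) {
    l <- lines[ln]
    if (nchar(l) < 54) {
      abort(sprintf("malformed PDB record at line %d: fewer than 54 columns", ln))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)
    )))
    if (anyNA(xyz)) {
      abort(sprintf("malformed PDB record at line %d: non-numeric coordinates", ln))
    }
  }
  length(coord)
}

# altloc policy: keep the highest-occupancy conformer, first on tie
resolve_altloc <- function(atoms) {
  atoms %>%
    group_by(.data$chain, .data$resnum, .data$icode, .data$res_name, .data$name) %>%
    arrange(dplyr::desc(.data$occupancy), .data$serial, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(.data$serial)
}

element_from_name <- function(name) {
  e <- toupper(trimws(name))
  two <- substr(e, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
    paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
    substr(sub("^[0-9]+", "", e), 1, 1)
  )
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (first model of multi-model files) with bio3d,
#' resolves alternate locations to the highest-occupancy conformer, and
#' extracts hetero groups of at least four heavy atoms as ligands; waters are
#' never ligands.
#'
#' @param path Path to a PDB file.
#' @param id Structure id; defaults to the file name.
#' @return A [mol_structure()].
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  n_coord <- validate_pdb_lines(lines)
  if (n_coord == 0) abort(paste0("no ATOM/HETATM records in ", path))
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  )
  at <- pdb$atom
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | !nzchar(elem)
  if (any(blank)) elem[blank] <- element_from_name(at$elety[blank])
  elem <- paste0(
    toupper(substr(elem, 1, 1)),
    tolower(substr(elem, 2, nchar(elem)))
  )
  atoms <- tibble(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt) | !nzchar(trimws(at$alt)), "", trimws(at$alt)),
    res_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(trimws(at$chain)), "A", trimws(at$chain)),
    resnum = at$resno,
    icode = ifelse(is.na(at$insert) | !nzchar(trimws(at$insert)), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = elem,
    hetero = at$type == "HETATM"
  )
  atoms <- resolve_altloc(atoms)
  prot <- atoms %>% filter(!.data$hetero)
  hets <- atoms %>% filter(.data$hetero)
  lig_groups <- hets %>%
    filter(!.data$res_name %in% WATER_NAMES) %>%
    group_by(.data$chain, .data$resnum, .data$icode, .data$res_name) %>%
    filter(sum(.data$element != "H") >= 4) %>%
    ungroup()
  other_het <- dplyr::anti_join(
    hets, lig_groups,
    by = c("chain", "resnum", "icode", "res_name", "serial")
  )
  ligands <- lig_groups %>%
    group_by(.data$chain, .data$resnum, .data$icode, .data$res_name) %>%
    dplyr::group_split() %>%
    map(function(grp) {
      grp <- grp %>% filter(.data$element != "H")
      small_molecule(
        tibble(
          element = grp$element, charge = 0L,
          x = grp$x, y = grp$y, z = grp$z,
          aromatic = FALSE, h_count = 0L
        ),
        tibble(i = integer(), j = integer(), order = integer(), aromatic = logical()),
        id = paste(grp$res_name[1], grp$chain[1], grp$resnum[1], sep = "_"),
        name = grp$res_name[1]
      )
    })
  mol_structure(prot, ligands = ligands, het = other_het,
    id = id %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}

format_pdb_atom <- function(record, serial, name, res_name, chain, resnum,
                            icode, x, y, z, occupancy, element) {
  name_fmt <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
    paste0(" ", sprintf("%-3s", name))
  )
  sprintf(
    "%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial %% 100000, name_fmt, res_name, substr(chain, 1, 1),
    resnum %% 10000, ifelse(nzchar(icode), icode, " "),
    x, y, z, occupancy, 0, toupper(element)
  )
}

structure_pdb_lines <- function(structure, serial_start = 1L) {
  a <- structure$atoms
  serial <- seq_len(nrow(a)) + serial_start - 1L
  format_pdb_atom(
    "ATOM", serial, a$name, a$res_name, a$chain, a$resnum, a$icode,
    a$x, a$y, a$z, a$occupancy, a$element
  )
}

ligand_pdb_lines <- function(mol, serial_start, res_name = "LIG",
                             chain = "X", resnum = 1L) {
  xyz <- mol_coords(mol)
  n <- nrow(xyz)
  name <- paste0(toupper(mol$atoms$element), seq_len(n))
  format_pdb_atom(
    "HETATM", seq_len(n) + serial_start - 1L, substr(name, 1, 4),
    res_name, chain, resnum, "", xyz[, 1], xyz[, 2], xyz[, 3], 1, mol$atoms$element
  )
}

#' Write a structure to a PDB file
#'
#' @param structure A [mol_structure()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- c(structure_pdb_lines(structure), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein-ligand complex (or multi-model set of complexes)
#'
#' Protein ATOM records followed by ligand HETATM records, re-readable by
#' [read_pdb()].  When several poses are given, each complex is wrapped in
#' MODEL/ENDMDL records.
#'
#' @param structure A [mol_structure()].
#' @param pose A `small_mol` with coordinates, or a list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_complex <- function(structure, pose, path) {
  poses <- if (inherits(pose, "small_mol")) list(pose) else pose
  for (p in poses) {
    if (!inherits(p, "small_mol") || !mol_has_coords(p)) {
      abort("every pose must be a small_mol with 3D coordinates")
    }
  }
  one_model <- function(p) {
    prot <- structure_pdb_lines(structure)
    lig <- ligand_pdb_lines(
      p, serial_start = nrow(structure$atoms) + 1L,
      res_name = substr(toupper(gsub("[^A-Za-z0-9]", "", p$id)), 1, 3)
    )
    c(prot, lig)
  }
  lines <- if (length(poses) == 1) {
    c(one_model(poses[[1]]), "END")
  } else {
    c(
      unlist(map(seq_along(poses), function(k) {
        c(sprintf("MODEL     %4d", k), one_model(poses[[k]]), "ENDMDL")
      })),
      "END"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read pocket annotations from a TSV file
#'
#' Expected columns: `target_id`, `chain`, `resnum`, `resname`, `confidence`
#' (percent).  One annotation per target; residue order is preserved.
#'
#' @param path Path to a tab-separated file with a header.
#' @return Named list of `pocket_annotation` objects (target id, residue
#'   tibble, confidence).
#' @export
read_pocket_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE)
  expected <- c("target_id", "chain", "resnum", "resname", "confidence")
  extra <- setdiff(names(df), expected)
  if (length(extra)) {
    abort(paste0("unknown column(s) in pocket annotation file: ",
      paste(extra, collapse = ", ")))
  }
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols)) {
    abort(paste0("pocket annotation file lacks column(s): ",
      paste(missing_cols, collapse = ", ")))
  }
  if (any(df$confidence < 0 | df$confidence > 100)) {
    abort("confidence must lie in [0, 100]")
  }
  ids <- unique(df$target_id)
  ann <- map(ids, function(tid) {
    rows <- df[df$target_id == tid, , drop = FALSE]
    conf <- unique(rows$confidence)
    if (length(conf) != 1) {
      abort(paste0("inconsistent confidence values for target ", tid))
    }
    pocket_annotation(
      target_id = tid,
      residues = tibble(
        chain = as.character(rows$chain),
        resnum = as.integer(rows$resnum),
        resname = as.character(rows$resname)
      ),
      confidence = conf
    )
  })
  setNames(ann, ids)
}

#' Pocket annotation
#'
#' A predicted binding site: a target id, an ordered list of binding residues,
#' a confidence percentage, and an optional precomputed center.
#'
#' @param target_id Target identifier.
#' @param residues Tibble with columns `chain`, `resnum`, `resname`.
#' @param confidence Percentage in \[0, 100\].
#' @param center Optional 3-vector (Angstrom).
#' @return An object of class `pocket_annotation`.
#' @export
pocket_annotation <- function(target_id, residues, confidence, center = NULL) {
  residues <- as_tibble(residues)
  if (nrow(residues) == 0) abort("annotation needs at least one residue")
  if (confidence < 0 || confidence > 100) abort("confidence must lie in [0, 100]")
  if (!is.null(center)) stopifnot(length(center) == 3, all(is.finite(center)))
  structure(
    list(target_id = target_id, residues = residues,
      confidence = as.numeric(confidence), center = center),
    class = "pocket_annotation"
  )
}

#' Write pocket annotations to TSV (mirror of the reader)
#' @param annotations List of `pocket_annotation` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pocket_annotations <- function(annotations, path) {
  rows <- bind_rows(map(annotations, function(a) {
    mutate(a$residues, target_id = a$target_id, confidence = a$confidence)
  }))
  rows <- rows[, c("target_id", "chain", "resnum", "resname", "confidence")]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
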