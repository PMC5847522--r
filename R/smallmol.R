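#' Small-molecule container
#'
#' A light molecular-graph container used throughout the package: a tibble of
#' atoms (element, formal charge, optional 3D coordinates in Angstrom,
#' aromatic flag, attached-hydrogen count) and a tibble of bonds (atom index
#' pair and integer order, with an aromatic flag).  Hydrogens are implicit:
#' only heavy atoms are stored, and `h_count` carries the number of attached
#' hydrogens so valence-dependent descriptors need no re-perception.
#'
#' @param atoms Tibble with columns `element`, `charge`, `x`, `y`, `z`,
#'   `aromatic`, `h_count`.  Coordinates may be `NA` (2D/graph-only input).
#' @param bonds Tibble with columns `i`, `j`, `order`, `aromatic`.
#' @param id,name Identifier and optional human-readable name.
#' @param sdf Optional SDF text backing the molecule (kept so OpenBabel-backed
#'   routines can reuse the exact input).
#' @return An object of class `small_mol`.
#' @export
small_molecule <- function(atoms, bonds, id = "mol", name = NULL, sdf = NULL) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  need <- c("element", "charge", "x", "y", "z", "aromatic", "h_count")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) < 1) abort("a molecule needs at least one heavy atom")
  if (!"aromatic" %in% names(bonds)) bonds$aromatic <- logical(nrow(bonds))
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 | bonds$j > nrow(atoms))) {
      abort("bond indices out of range")
    }
  }
  has_xyz <- !is.na(atoms$x) & !is.na(atoms$y) & !is.na(atoms$z)
  if (any(has_xyz) && !all(has_xyz)) {
    abort("either all heavy atoms carry coordinates or none do")
  }
  structure(
    list(id = id, name = name, atoms = atoms, bonds = bonds, sdf = sdf),
    class = "small_mol"
  )
}

#' @export
print.small_mol <- function(x, ...) {
  cat(sprintf(
    "<small_mol %s> %d heavy atoms, %d bonds, coords: %s\n",
    x$id, nrow(x$atoms), nrow(x$bonds),
    if (mol_has_coords(x)) "yes" else "no"
  ))
  invisible(x)
}

#' Does a molecule carry 3D coordinates?
#' @param mol A `small_mol`.
#' @return Logical flag.
#' @export
mol_has_coords <- function(mol) {
  nrow(mol$atoms) > 0 && !anyNA(mol$atoms$x)
}

#' Heavy-atom coordinate matrix of a molecule
#' @param mol A `small_mol` with coordinates.
#' @return An n x 3 numeric matrix (Angstrom).
#' @export
mol_coords <- function(mol) {
  if (!mol_has_coords(mol)) abort(paste0("molecule ", mol$id, " has no coordinates"))
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a molecule
#' @param mol A `small_mol`.
#' @param xyz An n x 3 matrix matching the heavy-atom count.
#' @return The molecule with updated coordinates.
#' @export
mol_set_coords <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(mol$atoms) || ncol(xyz) != 3) {
    abort("coordinate matrix must be n_atoms x 3")
  }
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# ---- OpenBabel adapters ------------------------------------------------------

# All chemical perception (SMILES parsing, aromaticity, hydrogen counts) is
# delegated to OpenBabel; these helpers only adapt its output.  Conversion runs
# through the obabel binary so hydrogen addition (-h) is available.
run_obabel <- function(infile, informat, outformat, extra = character()) {
  out <- suppressWarnings(system2(
    "obabel",
    c(paste0("-i", informat), shQuote(infile), paste0("-o", outformat), extra),
    stdout = TRUE, stderr = FALSE
  ))
  paste(out, collapse = "\n")
}

ob_convert_text <- function(text, informat, outformat, extra = character()) {
  tf <- tempfile(fileext = paste0(".", informat))
  on.exit(unlink(tf))
  writeLines(text, tf)
  run_obabel(tf, informat, outformat, extra)
}

parse_mol2_text <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")[1]
  b0 <- which(lines == "@<TRIPOS>BOND")[1]
  if (is.na(a0)) abort("no atoms in MOL2 output")
  sec_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt)) min(nxt) - 1 else length(lines)
  }
  atom_lines <- lines[(a0 + 1):sec_end(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- do.call(rbind, strsplit(trimws(atom_lines), "\\s+"))
  atoms <- tibble(
    type = af[, 6],
    element = sub("\\..*$", "", af[, 6]),
    aromatic = grepl("\\.ar$", af[, 6])
  )
  bonds <- tibble(i = integer(), j = integer(), order = integer(), aromatic = logical())
  if (!is.na(b0) && b0 + 1 <= sec_end(b0)) {
    bond_lines <- lines[(b0 + 1):sec_end(b0)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- do.call(rbind, strsplit(trimws(bond_lines), "\\s+"))
      bonds <- tibble(
        i = as.integer(bf[, 2]), j = as.integer(bf[, 3]),
        order = ifelse(bf[, 4] %in% c("ar", "am"), 1L,
          suppressWarnings(as.integer(bf[, 4]))
        ),
        aromatic = bf[, 4] == "ar"
      )
      ar_atoms <- unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))
      atoms$aromatic[ar_atoms] <- TRUE
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Parse a V2000 molblock for elements, coordinates, formal charges and bonds.
parse_sdf_v2000 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5) abort("malformed SDF block")
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) abort("malformed SDF counts line")
  al <- lines[5:(4 + n_atoms)]
  atoms <- tibble(
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)),
    element = trimws(substr(al, 32, 34)),
    charge = 0L
  )
  bonds <- if (!is.na(n_bonds) && n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    tibble(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    tibble(i = integer(), j = integer(), order = integer())
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- suppressWarnings(
      as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    )
    if (length(toks) >= 2) {
      idx <- toks[seq(1, length(toks), by = 2)]
      val <- toks[seq(2, length(toks), by = 2)]
      atoms$charge[idx] <- val
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' Read a small molecule from an SDF file or a SMILES string
#'
#' SDF input preserves 3D coordinates; SMILES input yields a graph without
#' coordinates (suitable for descriptor and fingerprint work only).
#' Aromaticity is perceived by OpenBabel; hydrogens are folded into per-atom
#' counts.
#'
#' @param x Path to an SDF file, or a SMILES string.
#' @param id Identifier to assign; defaults to the file name or the SMILES.
#' @return A [small_molecule()].
#' @export
read_small_molecule <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) == 1)
  is_file <- !grepl("\n", x) && file.exists(x) && !dir.exists(x)
  if (is_file) {
    src <- paste(readLines(x, warn = FALSE), collapse = "\n")
    informat <- "sdf"
    id <- id %||% sub("\\.(sdf|mol)$", "", basename(x), ignore.case = TRUE)
    has_coords <- TRUE
  } else {
    src <- x
    informat <- "smi"
    id <- id %||% x
    has_coords <- FALSE
  }
  mol2_txt <- ob_convert_text(src, informat, "mol2")
  if (!grepl("@<TRIPOS>ATOM", mol2_txt, fixed = TRUE)) {
    abort(paste0("unparsable molecular input '", substr(x, 1, 60), "'"))
  }
  g <- parse_mol2_text(mol2_txt)
  sdfh_txt <- ob_convert_text(src, informat, "sdf", extra = "-h")
  v <- parse_sdf_v2000(sdfh_txt)
  heavy <- which(v$atoms$element != "H")
  if (length(heavy) != nrow(g$atoms)) {
    abort("inconsistent OpenBabel output for molecular input")
  }
  idx_of <- rep(NA_integer_, nrow(v$atoms))
  idx_of[heavy] <- seq_along(heavy)
  h_count <- integer(length(heavy))
  if (nrow(v$bonds)) {
    for (k in seq_len(nrow(v$bonds))) {
      i <- v$bonds$i[k]
      j <- v$bonds$j[k]
      if (v$atoms$element[i] == "H" && !is.na(idx_of[j])) {
        h_count[idx_of[j]] <- h_count[idx_of[j]] + 1L
      } else if (v$atoms$element[j] == "H" && !is.na(idx_of[i])) {
        h_count[idx_of[i]] <- h_count[idx_of[i]] + 1L
      }
    }
  }
  # heavy-atom bonds with kekulized orders from the SDF block
  hb <- v$bonds[!is.na(idx_of[v$bonds$i]) & !is.na(idx_of[v$bonds$j]), , drop = FALSE]
  bonds <- tibble(
    i = idx_of[hb$i], j = idx_of[hb$j], order = hb$order,
    aromatic = FALSE
  )
  # SYBYL "ar" covers conjugated groups (e.g. carboxyl); restrict the aromatic
  # flag to ring atoms so it means ring aromaticity
  in_ring <- ring_membership(length(heavy), bonds)
  aromatic <- g$atoms$aromatic & in_ring
  bonds$aromatic <- aromatic[bonds$i] & aromatic[bonds$j] &
    ring_bond(bonds, in_ring)
  atoms <- tibble(
    element = g$atoms$element,
    charge = as.integer(v$atoms$charge[heavy]),
    x = if (has_coords) v$atoms$x[heavy] else NA_real_,
    y = if (has_coords) v$atoms$y[heavy] else NA_real_,
    z = if (has_coords) v$atoms$z[heavy] else NA_real_,
    aromatic = aromatic,
    h_count = h_count
  )
  small_molecule(atoms, bonds, id = id, sdf = if (is_file) src else sdfh_txt)
}

# ring (cycle) membership via 2-core pruning of the heavy-atom graph
ring_membership <- function(n_atoms, bonds) {
  deg <- integer(n_atoms)
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  alive <- rep(TRUE, n_atoms)
  repeat {
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    for (l in leaves) {
      alive[l] <- FALSE
      for (nb in adj[[l]]) if (alive[nb]) deg[nb] <- deg[nb] - 1L
      deg[l] <- 0L
    }
  }
  alive
}

ring_bond <- function(bonds, in_ring) {
  in_ring[bonds$i] & in_ring[bonds$j]
}

# minimal V2000 writer, used to hand programmatically built molecules to the
# OpenBabel-backed routines (fingerprints, logP)
mol_to_sdf <- function(mol) {
  if (!is.null(mol$sdf)) return(mol$sdf)
  a <- mol$atoms
  b <- mol$bonds
  xyz <- cbind(
    ifelse(is.na(a$x), 0, a$x), ifelse(is.na(a$y), 0, a$y),
    ifelse(is.na(a$z), 0, a$z)
  )
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    xyz[, 1], xyz[, 2], xyz[, 3], a$element
  )
  bond_lines <- if (nrow(b)) {
    sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, ifelse(b$aromatic, 4L, b$order))
  } else {
    character()
  }
  chg_lines <- character()
  charged <- which(a$charge != 0)
  if (length(charged)) {
    chg_lines <- sprintf(
      "M  CHG%3d%s", length(charged),
      paste0(sprintf(" %3d %3d", charged, a$charge[charged]), collapse = "")
    )
  }
  paste(c(mol$id, "  pocketrepo", "", counts, atom_lines, bond_lines, chg_lines,
    "M  END", "$$$$"), collapse = "\n")
}
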