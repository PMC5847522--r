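test_that("PDB reading populates chains, residues and ligands", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  st <- read_pdb(path)
  expect_s3_class(st, "mol_structure")
  expect_equal(nrow(structure_residues(st)), 3)
  expect_length(st$ligands, 1)
  expect_equal(nrow(st$ligands[[1]]$atoms), 5)
  # waters are never ligands
  expect_true(all(st$het$res_name == "HOH"))
})

test_that("a file containing only waters yields no ligands", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line("HETATM", 1, "O", "HOH", "A", 1, 0, 0, 0, element = "O"),
    pdb_atom_line("HETATM", 2, "O", "HOH", "A", 2, 3, 0, 0, element = "O"),
    "END"
  ), path)
  st <- read_pdb(path)
  expect_length(st$ligands, 0)
})

test_that("hetero groups below 4 heavy atoms are not ligands", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line("HETATM", 2, "C1", "ACT", "A", 50, 1, 1, 1),
    pdb_atom_line("HETATM", 3, "C2", "ACT", "A", 50, 2, 1, 1),
    pdb_atom_line("HETATM", 4, "O1", "ACT", "A", 50, 2, 2, 1, element = "O"),
    "END"
  ), path)
  st <- read_pdb(path)
  expect_length(st$ligands, 0)
  expect_equal(nrow(st$het), 3)
})

test_that("malformed records fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2      bad coords",
    "END"
  ), path)
  expect_error(read_pdb(path), "line 2")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_pdb(empty), "no ATOM/HETATM")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  l1 <- pdb_atom_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.4)
  l2 <- pdb_atom_line("ATOM", 2, "CA", "GLY", "A", 1, 5, 0, 0, occ = 0.6)
  substr(l1, 17, 17) <- "A"
  substr(l2, 17, 17) <- "B"
  writeLines(c(l1, l2, pdb_atom_line("ATOM", 3, "CA", "GLY", "A", 2, 1, 1, 1),
    "END"), path)
  st <- read_pdb(path)
  ca1 <- st$atoms[st$atoms$resnum == 1, ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 5)
})

test_that("write_complex round-trips coordinates to 3 decimals", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  st <- read_pdb(path)
  pose <- coords_mol(
    matrix(c(1.1234, 2.5678, 3.999, 2.345, 3.456, 4.567, 0.1, 0.2, 0.3,
      5.5, 6.6, 7.7), 4, 3, byrow = TRUE),
    elements = c("C", "N", "O", "C"), id = "pose"
  )
  out <- withr::local_tempfile(fileext = ".pdb")
  write_complex(st, pose, out)
  st2 <- read_pdb(out)
  expect_length(st2$ligands, 1)
  expect_equal(nrow(st2$ligands[[1]]$atoms), 4)
  expect_equal(mol_coords(st2$ligands[[1]]), round(mol_coords(pose), 3),
    tolerance = 1e-9)
  # protein coordinates survive too
  expect_equal(st2$atoms$x, round(st$atoms$x, 3), tolerance = 1e-9)
  # ligand partition is idempotent under re-write/re-read
  out2 <- withr::local_tempfile(fileext = ".pdb")
  write_complex(st2, st2$ligands[[1]], out2)
  st3 <- read_pdb(out2)
  expect_length(st3$ligands, 1)
  expect_equal(nrow(st3$ligands[[1]]$atoms), 4)
})

test_that("multi-pose complexes are written as MODEL/ENDMDL records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  st <- read_pdb(path)
  pose <- coords_mol(matrix(rnorm(12), 4, 3), id = "pose")
  pose2 <- coords_mol(matrix(rnorm(12), 4, 3), id = "pose")
  out <- withr::local_tempfile(fileext = ".pdb")
  write_complex(st, list(pose, pose2), out)
  lines <- readLines(out)
  expect_equal(sum(startsWith(lines, "MODEL")), 2)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 2)
  expect_error(write_complex(st, read_small_molecule("CCO"), out), "coordinates")
})

test_that("SMILES and SDF inputs parse to consistent graphs", {
  m <- read_small_molecule("CC(=O)O")
  expect_equal(nrow(m$atoms), 4)
  expect_equal(sum(m$bonds$order == 2), 1)
  expect_false(mol_has_coords(m))
  # SDF of the same molecule carries coordinates, same graph
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "acetic acid", "  test", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000   -1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  2  4  1  0  0  0  0",
    "M  END", "$$$$"
  ), sdf)
  m2 <- read_small_molecule(sdf)
  expect_equal(nrow(m2$atoms), 4)
  expect_equal(sum(m2$bonds$order == 2), 1)
  expect_true(mol_has_coords(m2))
  expect_equal(m2$atoms$x[2], 1.5)
  expect_error(read_small_molecule("C1CC"), "unparsable")
})

test_that("pocket annotation TSV round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "target_id\tchain\tresnum\tresname\tconfidence",
    "blk\tA\t10\tLEU\t99.2",
    "blk\tA\t25\tASP\t99.2",
    "other\tA\t10\tLEU\t55",
    "other\tA\t25\tASP\t55"
  ), path)
  ann <- read_pocket_annotations(path)
  expect_length(ann, 2)
  expect_equal(nrow(ann$blk$residues), 2)
  expect_equal(ann$blk$confidence, 99.2)
  # same residues under two targets stay two annotations
  expect_equal(ann$other$residues$resnum, c(10L, 25L))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pocket_annotations(ann, out)
  expect_equal(read_pocket_annotations(out)$blk$residues,
    ann$blk$residues)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "target_id\tchain\tresnum\tresname\tconfidence\tmystery",
    "x\tA\t1\tGLY\t50\t1"
  ), bad)
  expect_error(read_pocket_annotations(bad), "unknown column")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "target_id\tchain\tresnum\tresname\tconfidence",
    "x\tA\t1\tGLY\t105"
  ), bad2)
  expect_error(read_pocket_annotations(bad2), "confidence")
})
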