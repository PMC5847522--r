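make_cage_structure <- function(center, n = 26, radius = 2) {
  # dense shell of pseudo-atoms enclosing `center`
  pts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  pts <- pts[rowSums(abs(pts)) > 0, ]
  pts <- pts / sqrt(rowSums(pts^2)) * radius
  xyz <- sweep(pts, 2, -center)
  mol_structure(tibble::tibble(
    serial = seq_len(nrow(xyz)), name = "CB", altloc = "", res_name = "ALA",
    chain = "A", resnum = seq_len(nrow(xyz)), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = "C", hetero = FALSE
  ), id = "cage")
}

test_that("template docking reproduces the template ligand exactly", {
  lig_xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.3, 0, 3.7, 1.4, 0.2), 4, 3,
    byrow = TRUE)
  lig <- coords_mol(lig_xyz, elements = c("C", "C", "N", "O"), id = "tmpl")
  st <- make_cage_structure(c(50, 50, 50))
  drug <- coords_mol(sweep(lig_xyz %*% t(rotz90), 2, -c(8, -3, 2)),
    elements = c("C", "C", "N", "O"), id = "drug")
  mapping <- tibble::tibble(template_atom = 1:4, drug_atom = 1:4)
  # identity global transform: pose equals template ligand coordinates
  tc <- template_complex(st, lig, rigid_transform(), mapping)
  pose <- template_dock(st, tc, drug)
  expect_equal(mol_coords(pose$drug), lig_xyz, tolerance = 1e-9)
  # a known rigid global transform moves the pose with the template
  tr <- rigid_transform(rotz90, c(1, 2, 3))
  tc2 <- template_complex(st, lig, tr, mapping)
  pose2 <- template_dock(st, tc2, drug)
  expect_equal(mol_coords(pose2$drug), apply_transform(tr, lig_xyz),
    tolerance = 1e-9)
  expect_error(
    template_dock(st, template_complex(st, lig, rigid_transform(),
      mapping[1:2, ]), drug),
    "at least 3"
  )
})

test_that("unmapped drug atoms are carried rigidly", {
  lig_xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.3, 0), 3, 3, byrow = TRUE)
  lig <- coords_mol(lig_xyz, id = "tmpl")
  drug_xyz <- rbind(lig_xyz, c(2.9, 2.6, 0.4)) # one extra atom
  rot <- random_rotation()
  drug <- coords_mol(sweep(drug_xyz %*% t(rot), 2, -c(4, 4, 4)), id = "drug")
  st <- make_cage_structure(c(50, 50, 50))
  tc <- template_complex(st, lig, rigid_transform(),
    tibble::tibble(template_atom = 1:3, drug_atom = 1:3))
  pose <- template_dock(st, tc, drug)
  got <- mol_coords(pose$drug)
  expect_equal(got[1:3, ], lig_xyz, tolerance = 1e-8)
  # the extra atom keeps its internal geometry relative to the mapped ones
  expect_equal(
    as.numeric(dist(rbind(got[4, ], got[1, ]))),
    as.numeric(dist(rbind(drug_xyz[4, ], drug_xyz[1, ]))),
    tolerance = 1e-8
  )
})

test_that("alignment transfer is exactly rigid", {
  tp <- make_toy_pocket(n_residues = 8, seed = 41)
  res <- match_pockets(tp$pocket, tp$pocket)
  drug <- coords_mol(matrix(rnorm(18, sd = 2), 6, 3), id = "d")
  pose <- drug_pose(drug, source_id = "src", via = "self")
  moved <- transfer_by_alignment(pose, res$alignment)
  expect_equal(mol_coords(moved$drug), mol_coords(drug), tolerance = 1e-9)
  # a pure translation shifts every atom identically
  shifted <- pocket_alignment(
    res$alignment$pairs, rigid_transform(diag(3), c(10, 0, 0)),
    aligned_rmsd = 0
  )
  moved2 <- transfer_by_alignment(pose, shifted)
  expect_equal(mol_coords(moved2$drug), mol_coords(drug) +
    matrix(rep(c(10, 0, 0), each = 6), 6, 3), tolerance = 1e-12)
  # intra-ligand distances preserved under any transfer
  rnd <- pocket_alignment(
    res$alignment$pairs, rigid_transform(rotz90, c(3, -2, 8)), aligned_rmsd = 0
  )
  moved3 <- transfer_by_alignment(pose, rnd)
  expect_equal(as.numeric(dist(mol_coords(moved3$drug))),
    as.numeric(dist(mol_coords(drug))), tolerance = 1e-12)
  failed <- pocket_alignment(res$alignment$pairs, rigid_transform(),
    aligned_rmsd = 10, failed = TRUE)
  expect_error(transfer_by_alignment(pose, failed), "failed")
})

test_that("clash detection applies a strict cutoff", {
  st <- make_cage_structure(c(0, 0, 0), radius = 5)
  far <- drug_pose(coords_mol(rbind(c(50, 50, 50))), "s", "v")
  expect_equal(nrow(detect_clashes(far, st)), 0)
  # one protein atom at distance 1.0
  probe <- drug_pose(coords_mol(rbind(c(4, 0, 0))), "s", "v")
  cl <- detect_clashes(probe, st)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$distance, 1)
  # exactly at the cutoff: not a clash
  at_cut <- drug_pose(coords_mol(rbind(c(2.5, 0, 0))), "s", "v")
  st1 <- mol_structure(tibble::tibble(
    serial = 1L, name = "CB", altloc = "", res_name = "ALA", chain = "A",
    resnum = 1L, icode = "", x = 0, y = 0, z = 0, occupancy = 1,
    element = "C", hetero = FALSE
  ), id = "one")
  expect_equal(nrow(detect_clashes(at_cut, st1)), 0)
})

test_that("clash relief resolves resolvable clashes and caps displacement", {
  st1 <- mol_structure(tibble::tibble(
    serial = 1L, name = "CB", altloc = "", res_name = "ALA", chain = "A",
    resnum = 1L, icode = "", x = 0, y = 0, z = 0, occupancy = 1,
    element = "C", hetero = FALSE
  ), id = "one")
  # clash-free pose comes back unchanged, exactly
  free <- drug_pose(coords_mol(rbind(c(10, 0, 0), c(11, 0, 0))), "s", "v")
  out <- relieve_clashes(free, st1)
  expect_equal(mol_coords(out$pose$drug), mol_coords(free$drug))
  expect_true(out$relieved)
  expect_equal(out$displacement, 0)
  # single clash resolvable by a ~0.5 A shift
  near <- drug_pose(coords_mol(rbind(c(2.1, 0, 0), c(3.4, 0, 0))), "s", "v")
  out2 <- relieve_clashes(near, st1)
  expect_true(out2$relieved)
  expect_equal(nrow(detect_clashes(out2$pose, st1)), 0)
  expect_lte(out2$displacement, 1)
  # internal geometry untouched
  expect_equal(as.numeric(dist(mol_coords(out2$pose$drug))),
    as.numeric(dist(mol_coords(near$drug))), tolerance = 1e-12)
  # fully enclosed ligand: residual clashes reported, displacement capped
  cage <- make_cage_structure(c(0, 0, 0), radius = 2)
  stuck <- drug_pose(coords_mol(rbind(c(0, 0, 0))), "s", "v")
  out3 <- relieve_clashes(stuck, cage)
  expect_false(out3$relieved)
  expect_gt(nrow(out3$clashes), 0)
  expect_lte(out3$displacement, 3 + 1e-9)
})

test_that("clash relief never increases the overlap penalty", {
  set.seed(42)
  st <- make_cage_structure(c(0, 0, 0), radius = 4)
  pen <- function(pose) {
    cl <- detect_clashes(pose, st)
    sum((2.5 - cl$distance)^2)
  }
  for (k in 1:10) {
    start <- drug_pose(coords_mol(
      matrix(rnorm(9, sd = 2.5), 3, 3), id = "l"), "s", "v")
    out <- relieve_clashes(start, st)
    expect_lte(pen(out$pose), pen(start) + 1e-12)
  }
})

test_that("consensus picks the planted majority pose", {
  base <- matrix(rnorm(15, sd = 2), 5, 3)
  mk <- function(xyz) drug_pose(coords_mol(xyz, id = "d"), "s", "v")
  poses <- list(mk(base), mk(base), mk(base + 5 / sqrt(3)))
  cons <- consensus_pose(poses)
  expect_equal(cons$typical_index, 1L) # lowest index among the identical pair
  expect_equal(cons$rmsd_matrix[1, 2], 0)
  expect_equal(cons$rmsd_matrix[1, 3], 5, tolerance = 1e-9)
  expect_equal(cons$spread[1], 2.5, tolerance = 1e-9)
  # all-identical poses: zero spread everywhere, first pose typical
  all_same <- consensus_pose(list(mk(base), mk(base), mk(base)))
  expect_equal(all_same$typical_index, 1L)
  expect_true(all(all_same$spread == 0))
  expect_error(consensus_pose(poses[1]), "at least 2")
})

test_that("consensus RMSD matrices satisfy the triangle inequality", {
  set.seed(43)
  mk <- function(xyz) drug_pose(coords_mol(xyz, id = "d"), "s", "v")
  poses <- lapply(1:5, function(i) mk(matrix(rnorm(12, sd = 3), 4, 3)))
  m <- consensus_pose(poses)$rmsd_matrix
  for (i in 1:5) {
    for (j in 1:5) {
      for (k in 1:5) {
        expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
      }
    }
  }
})
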